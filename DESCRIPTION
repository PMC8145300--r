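Package: acidstab
Title: Stability of Organic Molecules in Concentrated Sulfuric Acid
Version: 0.1.0
Authors@R: person("acidstab", "maintainers", email = "maintainers@example.org",
                  role = c("aut", "cre"))
Description: Functional-group-based prediction of organic molecule
    half-lives in concentrated sulfuric acid as a function of acid
    concentration and temperature, with an altitude-resolved cloud acid
    profile for Venus-like atmospheres, dataset-level stability and
    chemical-diversity statistics, exhaustive combinatorial structure
    enumeration under valence and ring constraints, and a synthetic-data
    module providing kinetics grids, molecule sets and atmosphere
    profiles with exact ground truth. Includes a native SMILES parser,
    canonicalizer and SMARTS-subset substructure matcher sized to this
    chemical space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
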