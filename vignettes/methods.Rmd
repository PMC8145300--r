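---
title: "Methods: half-life screening of organics in concentrated sulfuric acid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: half-life screening of organics in concentrated sulfuric acid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidstab)
```

## The model and its assumptions

The package estimates how long an organic molecule survives in
concentrated sulfuric acid (CSA) as a function of acid strength and
temperature. The model is deliberately empirical:

1. **Pseudo-first-order kinetics.** The solvent is in vast excess, so the
   decomposition of a solute motif follows first-order kinetics in the
   solute and its half-life is concentration-independent: `t = ln 2 / k`.
2. **Group additivity.** Reactivity is carried by functional groups
   (reactive motifs), not whole molecules. Each group has its own rate
   surface over acid wt% and temperature.
3. **Fastest-group rule.** A molecule decomposes at the rate of its
   fastest-reacting group: its half-life is the minimum of its per-group
   half-lives, and that group is reported as *limiting*.
4. **Independent copies.** A group occurring N times reacts independently
   at each site, shortening the half-life to `t = -ln(1 - 0.5^N) / k`.
   Where independence is chemically wrong (1,2-diols), a compound group
   covering the correlated pair is defined instead and given precedence
   over its constituents.

The model claims order-of-magnitude accuracy at best; tests and
comparisons therefore work on `log10` half-lives. Pressure effects,
protonation-state prediction, mixture cross-reactions and solubility are
all out of scope.

### The multi-copy exponent

The multi-copy correction is implemented exactly as
`t = -ln(1 - 0.5^N)/k` and is isolated in a single function
(`half_life_multi`) so the reading can be swapped if the underlying data
source resolves it differently. This reading was chosen because it
reduces to the single-copy formula at `N = 1` and is strictly decreasing
in N — a molecule with more reactive sites dies faster — which is the
stated intent of the correction. The alternative typesetting
`0.5^(1/N)` fails the first property.

## Rate grids

Rate constants are stored as `ln k` on a grid of acid wt% × temperature
and interpolated **bilinearly in (wt%, 1/T)**: linear in inverse
temperature (Arrhenius) and linear in acidity on the log scale (the
standard empirical form for acid-catalyzed solvolysis, where rates climb
roughly one order of magnitude per 5–15 wt%). Queries outside the grid
are **clamped to the nearest edge and flagged** rather than extrapolated:
measured data are sparse at low temperature, and a conservative clamp
cannot manufacture spurious orders of magnitude. The flag is carried
through to per-molecule results (`extrapolated`).

`validate_grid` warns when a grid's rates decrease with temperature
(physically disallowed) but is silent about non-monotonic acid
dependence, which is chemically real (e.g. water activity effects).

The concentration symbol that appears in the underlying rate law cancels
in the half-life computation (first-order kinetics) and has no data
representation anywhere in the package.

## The cloud acid profile

Droplets are assumed to be in vapor equilibrium with atmospheric water.
The empirical relation used is, with `ppH2O` in mmHg and `T` in K:

```
P = (ln(ppH2O) - 15.988 - 42.2/T) / (0.053346 - 84.03/T)
```

The two temperature terms are read as *divided by* T. This reading is a
deliberate decision, isolated in one function (`acid_wt_pct`): it yields
Venus-plausible concentrations (roughly 80–105 % across cloud
temperatures and humidities) with the correct signs — drier or colder
air means stronger acid — whereas the multiplicative reading collapses
the result to ≈0.5 % regardless of input. Implementers wiring in real
data should spot-check against published water-vapor-pressure tables
over sulfuric acid. Values above 100 % are returned as-is and denote
fuming acid (oleum).

Profiles interpolate temperature and `ln(ppH2O)` linearly in altitude
and **recompute** the acid percentage from the interpolated inputs, so
the equilibrium relation holds exactly at every queried altitude
(interpolating P directly would violate it between levels).

## Molecule handling

There is no R cheminformatics dependency, so the package carries its own
SMILES reader, canonicalizer and SMARTS-subset matcher, sized to this
chemical space (C, H, N, O, S, P, Si, halogens; allowed valences C 4,
N 3, O 2, S 2/4/6, P 3/5, Si 4, halogens 1, shifted by formal charge).
Policies, each of which is an artifact decision rather than a claim
about how the original datasets were curated:

* **Salts/mixtures**: multi-component input keeps the largest covalent
  component (tie → first). The stability model operates on one covalent
  structure.
* **Stereochemistry** is parsed and discarded; nothing downstream is
  stereo-dependent.
* **Aromaticity**: aromatic input is stored with a distinct aromatic
  bond order; aromatic and Kekulé encodings of the same ring are
  *different* structures to the canonicalizer (no aromaticity
  perception). Datasets should be consistently encoded.
* **Canonicalization** uses iterative neighbourhood refinement plus
  individualization of tied atoms, taking the lexicographically smallest
  certificate — equal graphs yield equal SMILES regardless of input
  atom order. Tests verify this property under random renumbering and
  check the induced equivalence relation against RDKit (via the system
  Python) on a fixture set.

Group matching runs every registry pattern and resolves overlaps
greedily in descending priority: an atom consumed by a higher-priority
group is unavailable to lower-priority groups; equal-priority matches
are kept when atom-disjoint. Copy counts N are **symmetry-distinct atom
sets** (deduplicated by atom-index set), not automorphisms — N counts
chemical copies. Glycerol under the default registry yields
`{1,2-diol: 1, alcohol: 1}`.

The default registry is ~20 illustrative motifs with placeholder
kinetics. It is a stand-in that makes the pipeline exercisable: the real
measured compilation of 130 groups lives in an external database and can
be loaded with `read_group_table` / `read_rate_table`.

## Exhaustive enumeration

`enumerate_structures` generates every molecule buildable from an atom
palette within a heavy-atom size range, excluding rings smaller than
`min_ring_size` (default 5). Conventions (adjustable in one place, since
the reference generator's exact conventions are not restated in the
source work): structures are **neutral, closed-shell Kekulé graphs**;
hydrogens are implicit fill-to-valence and do not count toward size; no
charges, radicals, stereoisomers or aromatic perception at generation.
Deduplication is by canonical SMILES of the finished structure.

The generator is a depth-first assignment of bond orders over all atom
pairs with valence and connectivity pruning. Its oracle
(`oracle_enumerate`, specs ≤ 5 heavy atoms) is an independent path:
every labelled tuple × every order assignment, no pruning, survivors
classed by graph isomorphism using igraph's canonical permutation with
vertex colors (bonds encoded as colored vertices). Count equality between
the two paths also cross-checks the canonicalizer, since a merge error
would change the main path's count.

The published reference run (palette C, N, O, H, Si; 3–8 heavy atoms;
rings ≥ 5) reports 435,682 structures. Recomputing that count requires
the 6–8-atom tail, which is outside this package's pure-R test budget;
the oracle-equivalence suite on ≤ 5-atom specs is the correctness
evidence, and any full-count attempt should report discrepancies
per-convention (bond-order multiset, strain rules, charge policy) rather
than tuning conventions toward the number.

## The synthetic world

The synthetic module exists so that every stage has exact ground truth.
What it emulates, and what it does not:

* **Rate grids** follow
  `ln k = a + b (W - W0) + c (1/T0 - 1/T)` with reference condition
  (85 wt%, 298 K). `c > 0` is enforced (rates always increase with
  temperature); `b` may be negative (rates generally, but not always,
  increase with acidity — the default parameter table includes one
  negative slope, amide). `a = ln(ln 2 / t_ref)` plants an exact
  reference half-life. Default `t_ref` values are order-of-magnitude
  placeholders reflecting qualitative acid lability (silyl ethers
  ~10⁻² s, esters/alcohols ~10 s, amines ~10⁸ s since they dissolve as
  inert ammonium salts); `b ∈ [-0.02, 0.25]` per wt%; `c ∈
  [7000, 11000]` K, i.e. activation energies of ~60–90 kJ/mol. The form
  is log-linear *by design* — it is a test harness, not a claim about
  real CSA kinetics, and every cell is labelled `synthetic`.
* **Molecule sets** are assembled from hand-written homologous templates
  whose only registry match is the planted group (plus an alkane
  `none` class), apportioned by largest-remainder rounding, so planted
  fractions are exact, not approximate. The default plan (25 % amine,
  20 % alcohol, 15 % ester, 10 % diol, 10 % ketone, 12 % ether, 8 % no
  group) gives a set with a known stable fraction and a known
  no-prediction count. The seed controls only the final shuffle, through
  an isolated RNG state (the global stream is untouched).
* **Atmosphere**: temperature falls piecewise-linearly 365 K at 45 km →
  240 K at 60 km → 230 K at 70 km — steep through the lower cloud,
  nearly flat at the top, which is the regime where acid changes
  dominate rate changes. Humidity (`ln ppH2O`) declines linearly below
  the knee (anchored so the derived acid falls from 105 % oleum at the
  base to 85 % at the knee) and at 0.08 nepers/km above it, slow enough
  that the derived acid keeps declining there (the acid-neutral rate at
  these temperatures is ≈0.12/km). The optional cloud-top dip steepens
  the humidity decline over the last 3 km by 3 nepers total, producing a
  local acid maximum (~+9 wt%) at the top level and hence the
  characteristic dip in half-life at the cloud top. With the dip
  disabled the acid profile is strictly decreasing.

What a green test establishes: the pipeline arithmetic — matching,
precedence, interpolation, the fastest-group rule, aggregation — is
exactly right on a world whose answers are known. What it does not
establish: anything about real CSA kinetics, the real Venus profile, or
the real datasets' stable fractions; those require the external measured
database and are declared not desk-reproducible.

## Aggregation choices

* **"Average half-life" is the geometric mean** (arithmetic available via
  `type = "arithmetic"`): half-lives span > 10 orders of magnitude and
  any arithmetic mean is dominated by a single stable outlier.
* **"Above 62 km"** means profile levels with altitude ≥ 62 km,
  per-level fractions averaged unweighted over levels (not pooled over
  molecule × level pairs) — the simplest reading.
* **No-prediction molecules** (no reactive group, or no grid for any
  matched group) are excluded from every average and fraction; their
  count is always reported alongside.
* **Stability bands** are `[0,1)`, `[1,10³)`, `[10³,10⁶)`, `[10⁶,10⁸)`,
  `[10⁸,∞)` seconds, left-closed so `t = 10⁸ s` counts as stable at the
  10⁸ s threshold, consistent with `fraction_stable`'s `t ≥ threshold`.
* **Bond types** are unordered element pairs plus bond order, including
  bonds to implicit hydrogen; aromatic is its own type, so the count is
  independent of the Kekulé structure chosen for an aromatic ring
  (toggle `kekule_aromatic = TRUE` for the alternating single/double
  reading). Countable bonds exclude bonds to hydrogen.
* **Element-wise stable fractions** combine datasets as a weighted mean
  with weights equal to dataset sizes (counts of parsed molecules),
  matching the stated worked example. Note this equals the pooled
  per-element fraction only when element prevalence is proportional to
  dataset size; explicit weights can be supplied.

## Numerical notes and degenerate inputs

* `half_life_single(0)` errors unless the caller opts into an `Inf`
  sentinel; negative rates always error. N must be an integer ≥ 1.
* The vapor relation's denominator vanishes near T ≈ 1575 K, far outside
  any cloud; queries within 1e-8 of the singularity error out.
* Single-level grid axes behave as everywhere-clamped (flagged) axes, not
  errors.
* The forward/inverse acid relation round-trips to 1e-9 relative over
  P ∈ [60, 110], T ∈ [200, 400] (tested on a dense grid).
* Equal-priority overlapping matches are kept in discovery order; since
  ties only occur between symmetry-equivalent alternatives of the same
  group, the resolved counts are order-independent.

## Known limitations

* The SMILES/SMARTS dialects are subsets (no recursive SMARTS, no
  stereo, no isotope semantics, elements limited to the supported
  valence table). Sufficient for this pipeline; not a general toolkit.
* No aromaticity perception: aromatic vs Kekulé input encodings of the
  same ring canonicalize differently and should not be mixed within a
  dataset. Tests exercise both encodings explicitly.
* Enumeration in pure R is practical to ~5–6 heavy atoms in test time;
  the full 8-atom reference count is reachable in principle but not
  recomputed here.
* The default registry and synthetic kinetics are placeholders by
  construction; swapping in measured tables via the CSV loaders is the
  intended production path.
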