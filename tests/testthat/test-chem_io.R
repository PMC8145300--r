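test_that("valid SMILES parse to the expected graphs", {
  r <- parse_molecule("CCO")
  expect_equal(r$parse_status, "ok")
  expect_equal(sum(r$mol$atoms$element == "C"), 2)
  expect_equal(sum(r$mol$atoms$element == "O"), 1)
  expect_equal(sum(r$mol$atoms$nH), 6)
  expect_equal(nrow(r$mol$bonds), 2)
})

test_that("multi-component input is reduced by the largest-component policy", {
  # counter-ion dropped before validation: same record as plain ethanol
  salt <- parse_molecule("CCO.[Na+]")
  expect_equal(salt$parse_status, "ok")
  expect_equal(canonical_form(salt), canonical_form(parse_molecule("CCO")))
  salt2 <- parse_molecule("CCO.O")
  expect_equal(canonical_form(salt2), canonical_form(parse_molecule("CCO")))
  kept <- parse_molecule("CCO.O", policy = parse_policy(component = "keep"))
  expect_equal(n_atoms(kept$mol), 4)
  expect_equal(parse_molecule("CCO.O", policy = parse_policy(component = "reject"))$parse_status,
               "rejected")
})

test_that("invalid input is rejected with a reason, never a crash", {
  expect_equal(parse_molecule("C(C)(C)(C)(C)C")$parse_status, "rejected")
  expect_match(parse_molecule("C(C)(C)(C)(C)C")$reason, "valence")
  expect_equal(parse_molecule("")$reason, "empty input")
  expect_equal(parse_molecule("C1CC")$parse_status, "rejected")   # open ring
  expect_equal(parse_molecule("C((C)C")$parse_status, "rejected") # bad branch
  expect_equal(parse_molecule("Xx")$parse_status, "rejected")
})

test_that("canonical forms identify equal structures and separate different ones", {
  cf <- function(s) canonical_form(parse_molecule(s))
  expect_identical(cf("OCC"), cf("CCO"))
  expect_identical(cf("OCC"), cf("C(O)C"))
  expect_false(cf("C1CCCCC1") == cf("CCCCCC"))
  expect_identical(cf("c1ccc2ccccc2c1"), cf("c1ccc2c(c1)cccc2"))
  expect_identical(cf("CC(=O)N"), cf("NC(C)=O"))
  # stereo markers are discarded
  expect_identical(cf("C/C=C/C"), cf("CC=CC"))
})

test_that("canonical form is invariant under atom renumbering", {
  smiles <- c("CC(=O)OC1=CC=CC=C1C(=O)O", "OCC(O)CO", "c1ccc2ccccc2c1",
              "CC(C)(C)O[Si](C)(C)C", "N#CCC#N", "O=P(O)(O)OC", "c1ccsc1")
  set.seed(42)
  for (s in smiles) {
    mol <- parse_molecule(s)$mol
    ref <- write_smiles(mol)
    for (rep in 1:5) {
      perm <- sample(n_atoms(mol))
      expect_identical(write_smiles(permute_mol(mol, perm)), ref)
    }
    # round trip: parse(write(x)) is a fixed point
    expect_identical(canonical_form(parse_molecule(ref)), ref)
  }
})

test_that("canonicalization agrees with RDKit on equality structure", {
  # pairs (a, b, same?): our canonical forms must equate exactly the pairs
  # that RDKit equates (values differ; the equivalence relation must not)
  pairs <- list(
    c("CCO", "OCC", TRUE), c("CCO", "CCC", FALSE),
    c("OCC(O)CO", "C(O)C(CO)O", TRUE),
    c("c1ccc2ccccc2c1", "c1ccc2c(c1)cccc2", TRUE),
    c("CC(=O)N", "NC(C)=O", TRUE), c("C1CCCCC1", "CCCCCC", FALSE),
    c("CC(C)C", "CCCC", FALSE), c("CSC", "CCS", FALSE))
  rd <- rdkit_canonical(unlist(lapply(pairs, function(p) p[1:2])))
  expect_false(is.null(rd))  # oracle must run in this environment
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    ours <- canonical_form(parse_molecule(p[1])) == canonical_form(parse_molecule(p[2]))
    theirs <- rd[2 * i - 1] == rd[2 * i]
    expect_identical(ours, theirs, info = paste(p[1], p[2]))
    expect_identical(ours, as.logical(p[3]), info = paste(p[1], p[2]))
  }
})

test_that("dataset loading accounts for every line and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# comment", "CCO\tethanol", "OCCO\tglycol", "notasmiles\tbad",
               "", "c1ccccc1\tbenzene"), tmp)
  ds <- load_dataset(tmp, format = "smiles")
  expect_equal(ds$n_input, 4)
  expect_equal(length(ds$records), 3)
  expect_equal(nrow(ds$rejections), 1)
  expect_equal(length(ds$records) + nrow(ds$rejections), ds$n_input)
  expect_equal(ds$rejections$id, "bad")

  out <- withr::local_tempfile(fileext = ".smi")
  save_dataset(ds$records, out)
  ds2 <- load_dataset(out)
  expect_identical(vapply(ds2$records, canonical_form, ""),
                   vapply(ds$records, canonical_form, ""))
  expect_identical(vapply(ds2$records, `[[`, "", "id"),
                   vapply(ds$records, `[[`, "", "id"))
})

test_that("csv loading works and malformed headers are a hard error", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = c("a", "b"), smiles = c("CCO", "CC=O")),
                   tmp, row.names = FALSE)
  ds <- load_dataset(tmp, format = "csv")
  expect_equal(length(ds$records), 2)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(load_dataset(bad, format = "csv"), "header|columns")
  expect_error(load_dataset("/nonexistent/file.smi"), "no such file")
})

test_that("deduplication by canonical form is idempotent", {
  recs <- lapply(c("CCO", "OCC", "C(O)C", "CCC"), parse_molecule)
  d1 <- dedup_records(recs)
  expect_equal(length(d1), 2)
  expect_identical(dedup_records(d1), d1)
})
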