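test_that("bond type sets match the textbook counts", {
  bt <- function(s) bond_type_set(parse_molecule(s))
  expect_setequal(bt("CC"), c("C-C", "C-H"))              # alkane: 2
  expect_length(bt("CC=C"), 3)                             # alkene: 3
  expect_setequal(bt("CC(=O)N"), c("C-C", "C-H", "C=O", "C-N", "H-N"))  # amide: 5
  expect_length(bt("CC(=O)N"), 5)
  expect_setequal(bt("C"), "C-H")
  # unordered pairs: C-N identical from either direction
  expect_identical(bt("CNC"), bt("CN"))
})

test_that("aromatic bonds are one distinct type, with a Kekule toggle", {
  benz <- parse_molecule("c1ccccc1")$mol
  expect_setequal(bond_type_set(benz), c("C:C", "C-H"))
  expect_setequal(bond_type_set(benz, kekule_aromatic = TRUE),
                  c("C-C", "C=C", "C-H"))
  # invariance under renumbering and H-explicit encodings
  expect_identical(bond_type_set(parse_molecule("C(C)(O)")$mol),
                   bond_type_set(parse_molecule("OCC")$mol))
  expect_identical(bond_type_set(parse_molecule("[CH3][CH2][OH]")$mol),
                   bond_type_set(parse_molecule("CCO")$mol))
})

test_that("countable bonds exclude bonds to hydrogen", {
  expect_equal(countable_bonds(parse_molecule("C1CCCCC1")), 6)  # cyclohexane
  expect_equal(countable_bonds(parse_molecule("c1ccccc1")), 6)  # benzene
  expect_equal(countable_bonds(parse_molecule("C")), 0)         # methane
  expect_equal(countable_bonds(parse_molecule("CCO")), 2)
})

test_that("mean bond diversity aggregates the stable subset per altitude", {
  recs <- list(parse_molecule("CCC", id = "alkane"),
               parse_molecule("CC=C", id = "alkene"))
  res <- data.frame(molecule_id = rep(c("alkane", "alkene"), 2),
                    altitude_km = rep(c(50, 60), each = 2),
                    half_life_s = c(10, 10, 1e6, 10),
                    status = "ok")
  d <- mean_bond_diversity(recs, res, threshold_s = 1)
  expect_equal(d$mean_bond_types[d$altitude_km == 50], 2.5)  # (2+3)/2
  d2 <- mean_bond_diversity(recs, res, threshold_s = 1e5)
  expect_equal(d2$mean_bond_types[d2$altitude_km == 60], 2)  # alkane only
  expect_true(is.na(d2$mean_bond_types[d2$altitude_km == 50]))
  expect_equal(d2$n_stable[d2$altitude_km == 50], 0)
})

test_that("element fractions weight datasets by size", {
  mk <- function(smis, ids) mapply(parse_molecule, smis, ids,
                                   SIMPLIFY = FALSE, USE.NAMES = FALSE)
  # dataset A: size 1 Si-bearing stable; dataset B: 3 Si-bearing, none stable
  A <- mk("C[SiH3]", "a1")
  B <- mk(c("CC[SiH3]", "CCC[SiH3]", "CCCC[SiH3]"), c("b1", "b2", "b3"))
  resA <- data.frame(molecule_id = "a1", altitude_km = 60,
                     half_life_s = 1e9, status = "ok")
  resB <- data.frame(molecule_id = c("b1", "b2", "b3"), altitude_km = 60,
                     half_life_s = 10, status = "ok")
  ef <- element_stability_fractions(list(A = A, B = B),
                                    list(A = resA, B = resB), 1e8)
  si <- ef[ef$element == "Si", ]
  expect_equal(si$fraction_stable, (1 * 1 + 3 * 0) / 4)  # size-weighted
  expect_equal(si$n_with_element, 4)
  # explicit-weight override reproduces the stated worked example:
  # sizes 100 and 300 with fractions 0.2 and 0.6 combine to 0.5
  ef2 <- element_stability_fractions(list(A = A, B = B),
                                     list(A = resA, B = resB), 1e8,
                                     weights = c(A = 100, B = 300))
  # A fraction 1, B fraction 0 -> (100*1 + 300*0)/400
  expect_equal(ef2$fraction_stable[ef2$element == "Si"], 0.25)
  expect_equal((100 * 0.2 + 300 * 0.6) / 400, 0.5)
})

test_that("element present only in unstable molecules reports zero", {
  recs <- list(parse_molecule("CCS", id = "s1"))
  res <- data.frame(molecule_id = "s1", altitude_km = 55,
                    half_life_s = 0.1, status = "ok")
  ef <- element_stability_fractions(list(d = recs), list(d = res), 1)
  expect_equal(ef$fraction_stable[ef$element == "S"], 0)
})

test_that("equal-prevalence datasets give weighted equal to pooled fraction", {
  mk <- function(smis, ids) mapply(parse_molecule, smis, ids,
                                   SIMPLIFY = FALSE, USE.NAMES = FALSE)
  A <- mk(c("CS", "CCS"), c("a1", "a2"))
  B <- mk(c("CCCS", "CCCCS"), c("b1", "b2"))
  resA <- data.frame(molecule_id = c("a1", "a2"), altitude_km = 60,
                     half_life_s = c(1e9, 1), status = "ok")
  resB <- data.frame(molecule_id = c("b1", "b2"), altitude_km = 60,
                     half_life_s = c(1e9, 1e9), status = "ok")
  ef <- element_stability_fractions(list(A = A, B = B),
                                    list(A = resA, B = resB), 1e8)
  pooled <- 3 / 4
  expect_equal(ef$fraction_stable[ef$element == "S"], pooled)
})
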