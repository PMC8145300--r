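test_that("synthetic grids realize the stated closed form and monotonicity", {
  params <- data.frame(group_id = "g", t_ref = 100, b = 0.1, c = 8000)
  rates <- gen_rate_grids(params, W0 = 85, T0 = 298)
  g <- rates$g
  expect_length(validate_grid(g), 0)
  # half-life at the reference condition is exactly t_ref
  k <- rate_at(g, condition(85, 298))
  expect_equal(half_life_single(as.numeric(k)), 100, tolerance = 1e-9)
  # closed form at an off-reference node
  k2 <- as.numeric(rate_at(g, condition(100, 340)))
  expect_equal(log(k2), log(log(2) / 100) + 0.1 * 15 + 8000 * (1 / 298 - 1 / 340))
  # negative acid slope is allowed; non-positive temperature slope is not
  expect_silent(gen_rate_grids(data.frame(group_id = "g", t_ref = 1, b = -0.2, c = 1000)))
  expect_error(gen_rate_grids(data.frame(group_id = "g", t_ref = 1, b = 0.1, c = 0)),
               "c must be")
})

test_that("molecule sets realize planted fractions exactly", {
  plan <- data.frame(group_id = c("amine", "alcohol", "none"),
                     fraction = c(0.25, 0.60, 0.15))
  ds <- gen_molecule_set(100, plan, seed = 4)
  expect_length(ds$records, 100)
  expect_equal(sum(ds$truth$group_id == "amine"), 25)
  expect_equal(sum(ds$truth$group_id == "alcohol"), 60)
  expect_equal(sum(ds$truth$group_id == "none"), 15)
  # each molecule matches exactly its planted group (or nothing)
  reg <- default_registry()
  for (i in seq_along(ds$records)) {
    m <- match_groups(ds$records[[i]], reg)
    planted <- ds$truth$group_id[ds$truth$id == ds$records[[i]]$id]
    if (planted == "none") expect_equal(m$status, "no_reactive_groups")
    else expect_equal(m$assignments$group_id, planted)
  }
  # largest-remainder rounding at a non-divisible n
  ds2 <- gen_molecule_set(7, data.frame(group_id = c("amine", "alcohol"),
                                        fraction = c(0.5, 0.5)), seed = 1)
  tab <- table(ds2$truth$group_id)
  expect_equal(sort(as.integer(tab)), c(3, 4))
})

test_that("generators are deterministic under a fixed seed", {
  a <- gen_molecule_set(40, seed = 9)
  b <- gen_molecule_set(40, seed = 9)
  expect_identical(vapply(a$records, canonical_form, ""),
                   vapply(b$records, canonical_form, ""))
  expect_identical(a$truth, b$truth)
  c <- gen_molecule_set(40, seed = 10)
  expect_false(identical(a$truth$group_id, c$truth$group_id))
  # grid + atmosphere generators are parameter-deterministic
  expect_identical(gen_rate_grids(), gen_rate_grids())
  expect_identical(as.data.frame(gen_atmosphere()), as.data.frame(gen_atmosphere()))
  # the global RNG stream is left untouched
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(gen_molecule_set(10, seed = 2)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("infeasible plans error", {
  expect_error(gen_molecule_set(10, data.frame(group_id = "amine", fraction = 1.2)),
               "sum")
  expect_error(gen_molecule_set(10, data.frame(group_id = "nosuch", fraction = 1)),
               "template")
})

test_that("synthetic atmosphere has the stated shape", {
  prof <- gen_atmosphere()
  expect_equal(nrow(prof), 26)
  expect_equal(range(prof$altitude_km), c(45, 70))
  expect_true(all(diff(prof$temperature_K) < 0))
  expect_true(all(diff(log(prof$ppH2O_mmHg)) < 0))
  expect_true(all(prof$acid_wt_pct >= 70 & prof$acid_wt_pct <= 110))
  expect_gt(max(prof$acid_wt_pct), 100)  # oleum at cloud base
  # dip enabled: local acid maximum at the top level
  n <- nrow(prof)
  expect_gt(prof$acid_wt_pct[n], prof$acid_wt_pct[n - 1] - 1e-9)
  expect_gt(prof$acid_wt_pct[n - 2], prof$acid_wt_pct[n - 3])
  # dip disabled: acid strictly decreasing with altitude
  nod <- gen_atmosphere(dip = FALSE)
  expect_true(all(diff(nod$acid_wt_pct) < 0))
  # profiles always satisfy the equilibrium round trip
  expect_equal(ppH2O_forward(prof$acid_wt_pct, prof$temperature_K),
               prof$ppH2O_mmHg, tolerance = 1e-9)
})

test_that("planted stable fractions and limiting groups are recovered", {
  reg <- default_registry()
  rates <- gen_rate_grids()
  prof <- gen_atmosphere()
  plan <- data.frame(group_id = c("amine", "alcohol", "diol_12"),
                     fraction = c(0.25, 0.45, 0.30))
  ds <- gen_molecule_set(80, plan, seed = 6)
  res <- profile_stability(ds$records, reg, rates, prof)
  expect_equal(fraction_stable(res, 1e8, 62), 0.25)
  merged <- merge(res, ds$truth, by.x = "molecule_id", by.y = "id")
  expect_true(all(merged$limiting_group == merged$group_id))
  # reference half-life recovery: a single-copy alcohol at the reference
  # condition has exactly the planted reference half-life
  r <- molecule_half_life(match_groups(parse_molecule("CCO"), reg), rates,
                          condition(85, 298))
  expect_equal(r$half_life_s, default_synth_params()$t_ref[
    default_synth_params()$group_id == "alcohol"], tolerance = 1e-9)
})
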