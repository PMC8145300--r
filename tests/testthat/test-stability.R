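test_that("fastest group limits the molecule half-life", {
  reg <- register_groups(list(
    functional_group("A", "A", "[OX2H][CX4]", 60),
    functional_group("B", "B", "[NX3]", 50)))
  rates <- list(A = flat_grid("A", 1e-3), B = flat_grid("B", 1e-6))
  # OCCCCN has one hydroxyl (A, N=1) and one amine (B, N=1); plant B with
  # N=2 via OCC(N)CN: A N=1, B N=2
  m <- match_groups(parse_molecule("OCC(N)CN"), reg)
  r <- molecule_half_life(m, rates, condition(80, 300))
  expect_equal(r$status, "ok")
  expect_equal(r$limiting_group, "A")
  expect_equal(r$half_life_s, 693.147, tolerance = 1e-4)
  # the slower group's would-be value: two copies at k = 1e-6
  expect_equal(half_life_multi(1e-6, 2), 287682, tolerance = 1e-3)
})

test_that("molecules without groups or without grids get no prediction", {
  reg <- toy_registry()
  rates <- list(alcohol = flat_grid("alcohol", 1e-3))
  r <- molecule_half_life(match_groups(parse_molecule("CCCC"), reg), rates,
                          condition(80, 300))
  expect_equal(r$status, "no_prediction")
  expect_true(is.na(r$half_life_s))
  # matched group with no grid in the library
  r <- molecule_half_life(match_groups(parse_molecule("OCCO"), reg), rates,
                          condition(80, 300))
  expect_equal(r$status, "no_prediction")
})

test_that("fastest-group rule equals a brute-force minimum on random draws", {
  reg <- default_registry()
  params <- default_synth_params()
  set.seed(101)
  for (draw in 1:200) {
    p <- params
    p$t_ref <- 10^stats::runif(nrow(p), -3, 9)
    p$b <- stats::runif(nrow(p), -0.1, 0.3)
    p$c <- stats::runif(nrow(p), 5000, 12000)
    rates <- gen_rate_grids(p)
    groups <- sample(p$group_id, sample(1:4, 1))
    Ns <- sample(1:3, length(groups), replace = TRUE)
    match <- structure(list(
      molecule_id = "x",
      assignments = {
        df <- data.frame(group_id = groups, N = Ns,
                         reaction_class = "solvolysis",
                         stringsAsFactors = FALSE)
        df$atom_sets <- replicate(nrow(df), list(), simplify = FALSE)
        df
      },
      status = "matched"), class = "match_result")
    cond <- condition(stats::runif(1, 60, 110), stats::runif(1, 210, 390))
    got <- molecule_half_life(match, rates, cond)
    # independent brute force from the synthetic closed form
    t_all <- mapply(function(g, N) {
      row <- p[p$group_id == g, ]
      lnk <- log(log(2) / row$t_ref) + row$b * (cond$acid_wt_pct - 85) +
        row$c * (1 / 298 - 1 / cond$temperature_K)
      -log(1 - 0.5^N) / exp(lnk)
    }, groups, Ns)
    expect_equal(got$half_life_s, min(t_all), tolerance = 1e-9)
    expect_equal(got$limiting_group, groups[which.min(t_all)])
  }
})

test_that("profile stability yields one deterministic row per molecule-level", {
  reg <- default_registry()
  rates <- gen_rate_grids()
  prof <- gen_atmosphere()
  ds <- gen_molecule_set(10, seed = 3)
  res <- profile_stability(ds$records, reg, rates, prof)
  expect_equal(nrow(res), 10 * nrow(prof))
  res2 <- profile_stability(ds$records, reg, rates, prof)
  expect_identical(res, res2)
  # duplicate molecules give identical results
  recs <- lapply(c("CCO", "CCO"), function(s) parse_molecule(s, id = s))
  r2 <- profile_stability(recs, reg, rates, prof)
  h <- split(r2$half_life_s, r2$altitude_km)
  for (v in h) expect_equal(v[1], v[2])
})

test_that("half-life is non-decreasing with altitude on a monotone world", {
  # all-positive acid slopes + T-monotone grids + profile with T and acid
  # both decreasing with altitude
  p <- default_synth_params()
  p$b <- abs(p$b)
  rates <- gen_rate_grids(p)
  prof <- gen_atmosphere(dip = FALSE)
  expect_true(all(diff(prof$temperature_K) < 0))
  expect_true(all(diff(prof$acid_wt_pct) < 0))
  ds <- gen_molecule_set(30, seed = 5)
  res <- profile_stability(ds$records, default_registry(), rates, prof)
  for (id in unique(res$molecule_id)) {
    sub <- res[res$molecule_id == id & res$status == "ok", ]
    if (!nrow(sub)) next
    sub <- sub[order(sub$altitude_km), ]
    expect_true(all(diff(log(sub$half_life_s)) > -1e-12), info = id)
  }
})

test_that("fraction_stable averages per level and excludes no-predictions", {
  res <- data.frame(
    molecule_id = rep(sprintf("m%d", 1:10), 2),
    altitude_km = rep(c(62, 65), each = 10),
    half_life_s = c(c(rep(1e9, 3), rep(10, 6), NA),
                    c(rep(1e9, 5), rep(10, 4), NA)),
    status = rep(c(rep("ok", 9), "no_prediction"), 2))
  expect_equal(fraction_stable(res, 1e8, 62), mean(c(3 / 9, 5 / 9)))
  expect_equal(fraction_stable(res, 0, 62), 1.0)
  # non-increasing in threshold
  th <- c(0, 1, 1e3, 1e8, 1e10)
  fr <- vapply(th, function(x) fraction_stable(res, x, 62), 0)
  expect_true(all(diff(fr) <= 0))
  expect_error(fraction_stable(res, 1, 80), "no qualifying")
})

test_that("mean half-life is geometric by default", {
  res <- data.frame(molecule_id = c("a", "b"), altitude_km = 50,
                    half_life_s = c(10, 1000), status = "ok")
  expect_equal(mean_half_life(res, 50), 100)
  expect_equal(mean_half_life(res, 50, type = "arithmetic"), 505)
  # adding a molecule at the current mean leaves the mean unchanged
  res3 <- rbind(res, data.frame(molecule_id = "c", altitude_km = 50,
                                half_life_s = 100, status = "ok"))
  expect_equal(mean_half_life(res3, 50), 100)
  expect_error(mean_half_life(res, 60), "no matched")
})

test_that("band histogram partitions matched molecules", {
  res <- data.frame(molecule_id = sprintf("m%d", 1:6), altitude_km = 50,
                    half_life_s = c(0.5, 0.9, 5, 5e4, 5e7, 2e8),
                    status = "ok")
  res$band <- as.character(stability_band(res$half_life_s))
  h <- band_histogram(res)
  expect_equal(sum(h$count), 6)
  expect_equal(h$count[h$band == "<1s"], 2)
  expect_equal(h$ln_count[h$band == "<1s"], log(2))
  expect_false(any(h$count == 0))
  # band boundaries: t = 1e8 is in the top band, t = 1 leaves <1s
  expect_equal(as.character(stability_band(c(1e8, 1, 0.999))),
               c(">1e8s", "1-1e3s", "<1s"))
})

test_that("dataset_summary reports counts, exclusions and fractions", {
  reg <- default_registry(); rates <- gen_rate_grids(); prof <- gen_atmosphere()
  ds <- gen_molecule_set(50, seed = 2)
  res <- profile_stability(ds$records, reg, rates, prof)
  s <- dataset_summary(res)
  expect_equal(nrow(s), nrow(prof))
  n_none <- sum(ds$truth$group_id == "none")
  expect_true(all(s$n_no_prediction == n_none))
  expect_true(all(s$n_matched == 50 - n_none))
  # fractions non-increasing across thresholds in every row
  fr <- as.matrix(s[, grep("^frac_ge_", names(s))])
  expect_true(all(apply(fr, 1, function(r) all(diff(r) <= 0))))
})
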