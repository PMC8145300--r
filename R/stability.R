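# Per-molecule, per-altitude half-lives and dataset-level stability
# summaries.
#
# A molecule's half-life under a condition is the minimum over its
# assigned groups of the multi-copy half-life; the group attaining the
# minimum is the limiting group ("fastest-group rule"). Molecules with no
# reactive groups, or whose groups all lack rate data, carry no prediction
# and are excluded from averages (their count is always reported).

#' Half-life bands used in the summaries
#'
#' Band edges in seconds; the five bands are
#' `<1 s`, `1-1e3 s`, `1e3-1e6 s`, `1e6-1e8 s`, `>1e8 s`
#' (left-closed on the lower edge, so t = 1e8 s falls in the top band).
#' @export
STABILITY_BANDS <- c(1, 1e3, 1e6, 1e8)

band_labels <- c("<1s", "1-1e3s", "1e3-1e6s", "1e6-1e8s", ">1e8s")

#' Classify a half-life into a stability band
#' @param t half-life in seconds (vectorized)
#' @return factor with the five band labels
#' @export
stability_band <- function(t) {
  cut(t, breaks = c(0, STABILITY_BANDS, Inf), labels = band_labels,
      right = FALSE)
}

#' Half-life of one molecule under one condition
#'
#' @param match a `match_result` from [match_groups()]
#' @param rates named list of [rate_grid()] objects (a rate library)
#' @param cond a [condition()]
#' @return a `stability_result` list: `molecule_id`, `half_life_s` (NA for
#'   no prediction), `limiting_group`, `limiting_N`, `band`, `status`
#'   (`"ok"` or `"no_prediction"`), `extrapolated`
#' @export
molecule_half_life <- function(match, rates, cond) {
  res <- list(molecule_id = match$molecule_id, half_life_s = NA_real_,
              limiting_group = NA_character_, limiting_N = NA_integer_,
              band = NA_character_, status = "no_prediction",
              extrapolated = FALSE)
  class(res) <- "stability_result"
  if (match$status == "no_reactive_groups") return(res)
  a <- match$assignments
  t_g <- rep(NA_real_, nrow(a)); ex <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    grid <- rates[[a$group_id[i]]]
    if (is.null(grid)) next
    k <- rate_at(grid, cond)
    ex[i] <- isTRUE(attr(k, "extrapolated"))
    t_g[i] <- half_life_multi(as.numeric(k), a$N[i])
  }
  if (all(is.na(t_g))) return(res)
  j <- which.min(t_g)
  res$half_life_s <- t_g[j]
  res$limiting_group <- a$group_id[j]
  res$limiting_N <- a$N[j]
  res$band <- as.character(stability_band(t_g[j]))
  res$status <- "ok"
  res$extrapolated <- ex[j]
  res
}

#' Stability of a dataset across an atmosphere profile
#'
#' One result row per (molecule, level); deterministic given inputs.
#'
#' @param records list of ok `molecule_record`s (a loaded dataset)
#' @param registry an `fg_registry`
#' @param rates a rate library (named list of [rate_grid()])
#' @param profile an `atmosphere_profile`
#' @return data.frame with columns `molecule_id`, `altitude_km`,
#'   `acid_wt_pct`, `temperature_K`, `half_life_s`, `limiting_group`,
#'   `limiting_N`, `band`, `status`, `extrapolated`
#' @export
profile_stability <- function(records, registry, rates, profile) {
  matches <- lapply(records, match_groups, registry = registry)
  rows <- vector("list", length(records) * nrow(profile))
  k <- 0L
  for (li in seq_len(nrow(profile))) {
    cond <- condition(profile$acid_wt_pct[li], profile$temperature_K[li])
    for (mi in seq_along(matches)) {
      r <- molecule_half_life(matches[[mi]], rates, cond)
      k <- k + 1L
      rows[[k]] <- data.frame(
        molecule_id = as.character(r$molecule_id),
        altitude_km = profile$altitude_km[li],
        acid_wt_pct = profile$acid_wt_pct[li],
        temperature_K = profile$temperature_K[li],
        half_life_s = r$half_life_s, limiting_group = r$limiting_group,
        limiting_N = r$limiting_N, band = r$band, status = r$status,
        extrapolated = r$extrapolated, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Fraction of a dataset stable at a threshold, averaged over high levels
#'
#' Per qualifying level (altitude >= `altitude_min`), the fraction of
#' molecules with a prediction whose half-life is at least `threshold_s`;
#' the unweighted mean over qualifying levels is returned. Molecules
#' without predictions are excluded from numerator and denominator.
#'
#' @param results data.frame from [profile_stability()]
#' @param threshold_s stability threshold in seconds
#' @param altitude_min lowest qualifying altitude (km); default 62
#' @return fraction between 0 and 1
#' @export
fraction_stable <- function(results, threshold_s, altitude_min = 62) {
  sub <- results[results$altitude_km >= altitude_min & results$status == "ok", ]
  if (!nrow(sub)) stop("no qualifying levels with matched molecules")
  per_level <- tapply(sub$half_life_s >= threshold_s, sub$altitude_km, mean)
  mean(per_level)
}

#' Average half-life of a dataset at one altitude
#'
#' Geometric mean by default (half-lives span many orders of magnitude);
#' arithmetic mean available for comparison.
#'
#' @param results data.frame from [profile_stability()]
#' @param altitude_km level to summarize
#' @param type `"geometric"` (default) or `"arithmetic"`
#' @return mean half-life in seconds
#' @export
mean_half_life <- function(results, altitude_km,
                           type = c("geometric", "arithmetic")) {
  type <- match.arg(type)
  sub <- results[results$altitude_km == altitude_km & results$status == "ok", ]
  if (!nrow(sub)) stop("no matched molecules at this altitude")
  if (type == "geometric") exp(mean(log(sub$half_life_s)))
  else mean(sub$half_life_s)
}

#' Counts of molecules per (altitude, stability band)
#'
#' @param results data.frame from [profile_stability()]
#' @return data.frame `altitude_km`, `band`, `count`, `ln_count`; zero
#'   cells are absent
#' @export
band_histogram <- function(results) {
  sub <- results[results$status == "ok", ]
  if (!nrow(sub))
    return(data.frame(altitude_km = numeric(0), band = character(0),
                      count = integer(0), ln_count = numeric(0)))
  tab <- as.data.frame(table(altitude_km = sub$altitude_km, band = sub$band),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  data.frame(altitude_km = as.numeric(tab$altitude_km), band = tab$band,
             count = tab$Freq, ln_count = log(tab$Freq),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-altitude dataset summary
#'
#' @param results data.frame from [profile_stability()]
#' @param thresholds stability thresholds in seconds
#' @return data.frame with per-altitude counts, geometric-mean half-life
#'   and stable fractions at each threshold
#' @export
dataset_summary <- function(results, thresholds = STABILITY_BANDS) {
  alts <- sort(unique(results$altitude_km))
  out <- lapply(alts, function(z) {
    sub <- results[results$altitude_km == z, ]
    ok <- sub[sub$status == "ok", ]
    row <- data.frame(altitude_km = z, n_matched = nrow(ok),
                      n_no_prediction = sum(sub$status != "ok"),
                      geomean_half_life_s =
                        if (nrow(ok)) exp(mean(log(ok$half_life_s))) else NA_real_)
    for (th in thresholds)
      row[[sprintf("frac_ge_%gs", th)]] <-
        if (nrow(ok)) mean(ok$half_life_s >= th) else NA_real_
    row
  })
  do.call(rbind, out)
}
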