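# Rate-constant grids over acid concentration and temperature, and the
# pseudo-first-order half-life model.
#
# Rate constants k (s^-1) are stored as ln k on a grid of acid wt% x
# temperature (K) and interpolated bilinearly in the coordinates
# (wt%, 1/T): Arrhenius-linear in inverse temperature and log-linear in
# acidity, the standard empirical forms. The model claims
# order-of-magnitude accuracy only; downstream comparisons work in log10.

#' A reaction condition
#' @param acid_wt_pct sulfuric acid concentration, percent by weight
#'   (values above 100 denote oleum)
#' @param temperature_K absolute temperature, kelvin
#' @return a `condition` list
#' @export
condition <- function(acid_wt_pct, temperature_K) {
  stopifnot(acid_wt_pct >= 0, temperature_K > 0)
  structure(list(acid_wt_pct = acid_wt_pct, temperature_K = temperature_K),
            class = "condition")
}

#' Construct a rate grid for one functional group
#'
#' @param group_id identifier matching a registry group
#' @param wt_levels ascending acid wt percent levels
#' @param T_levels ascending temperature levels (K)
#' @param ln_k matrix of natural-log rate constants (s^-1),
#'   `length(wt_levels)` rows by `length(T_levels)` columns
#' @param provenance `"measured"`, `"interpolated"` or `"synthetic"`
#'   (scalar or matrix of the same shape)
#' @return a `rate_grid`
#' @export
rate_grid <- function(group_id, wt_levels, T_levels, ln_k,
                      provenance = "synthetic") {
  wt_levels <- as.numeric(wt_levels); T_levels <- as.numeric(T_levels)
  ln_k <- matrix(as.numeric(ln_k), nrow = length(wt_levels),
                 ncol = length(T_levels))
  if (is.unsorted(wt_levels, strictly = TRUE) ||
      is.unsorted(T_levels, strictly = TRUE))
    stop("grid levels must be strictly ascending")
  if (!all(is.finite(ln_k))) stop("ln_k must be finite")
  structure(list(group_id = group_id, wt_levels = wt_levels,
                 T_levels = T_levels, ln_k = ln_k, provenance = provenance),
            class = "rate_grid")
}

#' Interpolate a rate constant from a grid
#'
#' Bilinear interpolation of ln k in (acid wt%, 1/T). Queries outside the
#' grid are clamped to the nearest edge and flagged; a single-level axis
#' behaves as an everywhere-clamped axis.
#'
#' @param grid a [rate_grid()]
#' @param cond a [condition()]
#' @return rate constant k in s^-1 (positive), with attribute
#'   `extrapolated` (logical)
#' @export
rate_at <- function(grid, cond) {
  clamp1 <- function(x, levels) {
    if (x < levels[1]) list(i = 1L, j = 1L, f = 0, clamped = TRUE)
    else if (x > levels[length(levels)])
      list(i = length(levels), j = length(levels), f = 0, clamped = TRUE)
    else {
      i <- max(which(levels <= x))
      if (i == length(levels)) list(i = i, j = i, f = 0, clamped = FALSE)
      else list(i = i, j = i + 1L,
                f = (x - levels[i]) / (levels[i + 1L] - levels[i]),
                clamped = FALSE)
    }
  }
  w <- clamp1(cond$acid_wt_pct, grid$wt_levels)
  # temperature axis interpolated linearly in 1/T
  invT <- rev(1 / grid$T_levels)             # ascending in 1/T
  ti <- clamp1(1 / cond$temperature_K, invT)
  nT <- length(grid$T_levels)
  col <- function(k) nT - k + 1L             # invT index -> T_levels index
  v11 <- grid$ln_k[w$i, col(ti$i)]; v12 <- grid$ln_k[w$i, col(ti$j)]
  v21 <- grid$ln_k[w$j, col(ti$i)]; v22 <- grid$ln_k[w$j, col(ti$j)]
  lo <- v11 * (1 - ti$f) + v12 * ti$f
  hi <- v21 * (1 - ti$f) + v22 * ti$f
  lnk <- lo * (1 - w$f) + hi * w$f
  structure(exp(lnk), extrapolated = w$clamped || ti$clamped)
}

#' Half-life of a first-order reaction
#'
#' t = -ln(0.5) / k = ln 2 / k.
#'
#' @param k rate constant, s^-1, positive
#' @param zero_ok when TRUE, k = 0 returns +Inf instead of an error
#' @return half-life in seconds
#' @export
half_life_single <- function(k, zero_ok = FALSE) {
  if (any(k < 0) || (!zero_ok && any(k == 0)))
    stop("rate constant must be positive")
  ifelse(k == 0, Inf, log(2) / k)
}

#' Half-life of a molecule with N copies of one reactive group
#'
#' Multi-copy correction t = -ln(1 - 0.5^N) / k, assuming independent
#' reaction of the copies. Reduces to [half_life_single()] at N = 1 and is
#' strictly decreasing in N. The exponent reading (0.5^N rather than
#' 0.5^(1/N)) is isolated here on purpose; see the methods vignette.
#'
#' @param k rate constant, s^-1, positive
#' @param N integer copy count, N >= 1
#' @return half-life in seconds
#' @export
half_life_multi <- function(k, N) {
  if (any(k <= 0)) stop("rate constant must be positive")
  if (any(N < 1) || any(N != as.integer(N))) stop("N must be an integer >= 1")
  -log(1 - 0.5^N) / k
}

#' Validate a rate grid against the expected monotonicities
#'
#' Rates must never decrease with temperature; acid-axis non-monotonicity
#' is chemically real and not warned about.
#'
#' @param grid a [rate_grid()]
#' @return character vector of warnings (empty when clean)
#' @export
validate_grid <- function(grid) {
  out <- character(0)
  for (i in seq_along(grid$wt_levels)) {
    row <- grid$ln_k[i, ]
    if (any(diff(row) < 0))
      out <- c(out, sprintf("group %s: ln_k decreases with temperature at wt %g%%",
                            grid$group_id, grid$wt_levels[i]))
  }
  out
}

#' Read a rate-table CSV into a rate library
#'
#' Long format with columns
#' `group_id,acid_wt_pct,temperature_K,ln_k,provenance`, pivoted into one
#' [rate_grid()] per group.
#'
#' @param path CSV file
#' @return named list of `rate_grid` (a "rate library")
#' @export
read_rate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group_id", "acid_wt_pct", "temperature_K", "ln_k")
  if (!all(need %in% names(df)))
    stop("rate table must have columns ", paste(need, collapse = ","))
  out <- list()
  for (g in unique(df$group_id)) {
    sub <- df[df$group_id == g, ]
    wt <- sort(unique(sub$acid_wt_pct)); Tk <- sort(unique(sub$temperature_K))
    m <- matrix(NA_real_, length(wt), length(Tk))
    m[cbind(match(sub$acid_wt_pct, wt), match(sub$temperature_K, Tk))] <- sub$ln_k
    if (any(is.na(m))) stop("incomplete grid for group ", g)
    prov <- if ("provenance" %in% names(df)) sub$provenance[1] else "measured"
    out[[g]] <- rate_grid(g, wt, Tk, m, prov)
  }
  out
}

#' Write a rate library to a long-format CSV
#' @param rates named list of `rate_grid`
#' @param path output CSV
#' @export
write_rate_table <- function(rates, path) {
  rows <- lapply(rates, function(g) {
    expand <- expand.grid(wi = seq_along(g$wt_levels), ti = seq_along(g$T_levels))
    data.frame(group_id = g$group_id,
               acid_wt_pct = g$wt_levels[expand$wi],
               temperature_K = g$T_levels[expand$ti],
               ln_k = g$ln_k[cbind(expand$wi, expand$ti)],
               provenance = if (length(g$provenance) == 1) g$provenance
                            else g$provenance[cbind(expand$wi, expand$ti)])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
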