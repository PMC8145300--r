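# Synthetic kinetics tables, molecule datasets, and atmosphere profiles
# with known ground truth, so every pipeline stage is testable without the
# external measured-kinetics database or the full public datasets.
#
# The synthetic rate law is log-linear by design:
#   ln k(W, T) = a_g + b_g (W - W0) + c_g (1/T0 - 1/T)
# with c_g > 0 enforcing the always-increase-with-temperature behaviour of
# the real data; b_g may be negative (rates generally, but not always,
# increase with acid concentration). It is a test harness, not a claim
# about real sulfuric-acid kinetics; every grid cell is labelled
# provenance "synthetic".

#' Default synthetic kinetic parameters for the default registry
#'
#' One row per group of [default_registry()]: reference half-life `t_ref`
#' (seconds) at the reference condition (85 wt%, 298 K), acid slope `b`
#' (per wt%), and temperature coefficient `c` (kelvin; an activation
#' energy over R, 6000-11000 K corresponding to roughly 50-90 kJ/mol).
#' Reference half-lives are order-of-magnitude placeholders reflecting
#' the qualitative acid lability of each motif (silyl ethers fastest,
#' protonated amines essentially inert).
#'
#' @return data.frame `group_id`, `t_ref`, `b`, `c`
#' @export
default_synth_params <- function() {
  p <- rbind(
    c("diol_12",      1e0,  0.20,  8000),
    c("carboxylic",   1e2,  0.15,  9000),
    c("ester",        1e1,  0.20,  8500),
    c("amide",        1e4, -0.02,  9500),
    c("anhydride",    1e-1, 0.25,  8000),
    c("aldehyde",     1e1,  0.15,  8500),
    c("ketone",       1e2,  0.15,  9000),
    c("phosphate_e",  1e0,  0.20,  8000),
    c("tms_ether",    1e-2, 0.25,  7000),
    c("nitrile",      1e5,  0.10, 10000),
    c("alcohol",      1e1,  0.20,  8000),
    c("thiol",        1e3,  0.10,  9000),
    c("amine",        1e8,  0.10,  8000),
    c("ether",        1e4,  0.15,  9500),
    c("thioether",    1e5,  0.10,  9500),
    c("alkyne",       1e2,  0.20,  8500),
    c("alkene",       1e3,  0.20,  8500),
    c("alkyl_halide", 1e6,  0.10, 10000),
    c("aromatic_ch",  1e7,  0.25, 11000)
  )
  data.frame(group_id = p[, 1], t_ref = as.numeric(p[, 2]),
             b = as.numeric(p[, 3]), c = as.numeric(p[, 4]),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic rate library
#'
#' Each group's grid is `ln k = a + b (W - W0) + c (1/T0 - 1/T)` with
#' `a = ln(ln 2 / t_ref)`, so that the half-life of a single copy at the
#' reference condition is exactly `t_ref`. Grids always pass
#' [validate_grid()] because `c > 0` is enforced.
#'
#' @param params data.frame `group_id`, `t_ref`, `b`, `c` (see
#'   [default_synth_params()])
#' @param wt_levels,T_levels grid axes
#' @param W0,T0 reference condition (85 wt%, 298 K by default)
#' @return named list of [rate_grid()] (a rate library)
#' @export
gen_rate_grids <- function(params = default_synth_params(),
                           wt_levels = seq(60, 115, by = 5),
                           T_levels = seq(200, 400, by = 20),
                           W0 = 85, T0 = 298) {
  if (any(params$c <= 0)) stop("temperature coefficient c must be > 0")
  out <- list()
  for (i in seq_len(nrow(params))) {
    a <- log(log(2) / params$t_ref[i])
    lnk <- outer(wt_levels, T_levels, function(W, Tk)
      a + params$b[i] * (W - W0) + params$c[i] * (1 / T0 - 1 / Tk))
    out[[params$group_id[i]]] <-
      rate_grid(params$group_id[i], wt_levels, T_levels, lnk, "synthetic")
  }
  out
}

# SMILES templates with known single-group content; index i >= 0 gives
# homologous distinct structures (alkyl chain growth only, so no second
# registry group is ever introduced).
.synth_templates <- list(
  amine     = function(i) paste0(strrep("C", 2 + i), "N"),
  alcohol   = function(i) paste0(strrep("C", 1 + i), "O"),
  ester     = function(i) paste0("CC(=O)O", strrep("C", 1 + i)),
  diol_12   = function(i) if (i == 0) "OCCO" else
                          paste0("OC(", strrep("C", i), ")CO"),
  ketone    = function(i) paste0("CC(=O)", strrep("C", 1 + i)),
  ether     = function(i) paste0("CO", strrep("C", 1 + i)),
  amide     = function(i) paste0("CC(=O)N", strrep("C", i)),
  nitrile   = function(i) paste0(strrep("C", 1 + i), "C#N"),
  thioether = function(i) paste0("CSC", strrep("C", i)),
  carboxylic = function(i) paste0(strrep("C", 1 + i), "C(=O)O"),
  none      = function(i) strrep("C", 3 + i)
)

#' Default composition plan for synthetic molecule sets
#'
#' Fractions of the dataset bearing each planted group; the `none` row is
#' the no-reactive-group fraction (alkanes). Fractions sum to 1.
#' @return data.frame `group_id`, `fraction`
#' @export
default_molecule_plan <- function() {
  data.frame(
    group_id = c("amine", "alcohol", "ester", "diol_12", "ketone",
                 "ether", "none"),
    fraction = c(0.25, 0.20, 0.15, 0.10, 0.10, 0.12, 0.08),
    stringsAsFactors = FALSE)
}

# Largest-remainder apportionment of n among fractions (ties by order).
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  counts <- floor(exact)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(-(exact - counts), seq_along(fractions))
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic molecule dataset with planted group content
#'
#' Molecules are assembled from hand-written fragment templates whose only
#' registry match is the planted group, so ground truth is exact: the
#' fraction bearing each group matches the plan under largest-remainder
#' rounding, and each molecule's limiting group is known.
#'
#' @param n dataset size (>= 1)
#' @param plan data.frame `group_id`, `fraction` (fractions sum to <= 1;
#'   any remainder goes to `none`); group ids must have templates
#' @param seed integer seed controlling the final shuffle only
#' @return list with `records` (parsed `molecule_record`s) and `truth`
#'   (data.frame `id`, `group_id`)
#' @export
gen_molecule_set <- function(n, plan = default_molecule_plan(), seed = 1L) {
  stopifnot(n >= 1)
  if (sum(plan$fraction) > 1 + 1e-9) stop("planted fractions must sum to <= 1")
  if (sum(plan$fraction) < 1 - 1e-9 && !"none" %in% plan$group_id)
    plan <- rbind(plan, data.frame(group_id = "none",
                                   fraction = 1 - sum(plan$fraction)))
  missing <- setdiff(plan$group_id, names(.synth_templates))
  if (length(missing)) stop("no template for group(s): ",
                            paste(missing, collapse = ", "))
  counts <- largest_remainder(n, plan$fraction)
  smi <- character(0); grp <- character(0)
  for (j in seq_len(nrow(plan))) {
    if (counts[j] == 0) next
    tpl <- .synth_templates[[plan$group_id[j]]]
    smi <- c(smi, vapply(seq_len(counts[j]) - 1L, tpl, ""))
    grp <- c(grp, rep(plan$group_id[j], counts[j]))
  }
  # deterministic shuffle under an isolated RNG state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  ord <- sample.int(length(smi))
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  smi <- smi[ord]; grp <- grp[ord]
  ids <- sprintf("syn%04d", seq_along(smi))
  records <- lapply(seq_along(smi), function(i) parse_molecule(smi[i], id = ids[i]))
  bad <- vapply(records, function(r) r$parse_status != "ok", TRUE)
  if (any(bad)) stop("internal: template produced unparseable SMILES")
  list(records = records,
       truth = data.frame(id = ids, group_id = grp, stringsAsFactors = FALSE))
}

#' Generate a synthetic Venus-like atmosphere profile
#'
#' Temperature decreases piecewise-linearly through declared knot points:
#' steeply through the lower cloud, nearly flat near the cloud top (the
#' regime where acid-concentration changes dominate reaction rates).
#' Humidity (ln ppH2O) declines piecewise-linearly with altitude: the
#' lower slope is set so the in-equilibrium acid concentration falls from
#' `acid_bottom` at the base to `acid_knee` at the temperature knee, and
#' the gentler `upper_lnp_slope` applies above the knee, chosen so the
#' derived acid concentration keeps declining there. The optional dip
#' applies an extra steep humidity decline over the last `dip_width` km,
#' producing a local acid maximum at the top level (the cloud-top
#' stability dip mechanism).
#'
#' @param altitudes ascending altitudes in km (default 45-70, 1 km steps)
#' @param T_knots data.frame `alt`, `T_K` of temperature knot points; the
#'   second knot is the knee
#' @param acid_bottom,acid_knee acid wt% at the first altitude and at the
#'   knee (the default spans oleum at cloud base to 85% mid-cloud)
#' @param upper_lnp_slope decline of ln(ppH2O) per km above the knee
#'   (nepers; must stay below the acid-neutral rate, about 0.12/km for the
#'   default temperatures)
#' @param dip apply the cloud-top humidity dip?
#' @param dip_mag extra decline of ln(ppH2O) at the top level (nepers)
#' @param dip_width width of the dip ramp in km
#' @return an `atmosphere_profile`
#' @export
gen_atmosphere <- function(altitudes = seq(45, 70, by = 1),
                           T_knots = data.frame(alt = c(45, 60, 70),
                                                T_K = c(365, 240, 230)),
                           acid_bottom = 105, acid_knee = 85,
                           upper_lnp_slope = 0.08,
                           dip = TRUE, dip_mag = 3, dip_width = 3) {
  stopifnot(!is.unsorted(altitudes, strictly = TRUE))
  z0 <- altitudes[1]; z1 <- altitudes[length(altitudes)]
  zk <- T_knots$alt[2]
  Tz <- stats::approx(T_knots$alt, T_knots$T_K, xout = altitudes, rule = 2)$y
  Tk <- stats::approx(T_knots$alt, T_knots$T_K, xout = zk, rule = 2)$y
  lnp0 <- log(ppH2O_forward(acid_bottom, Tz[1]))
  lnpk <- log(ppH2O_forward(acid_knee, Tk))
  lnp <- ifelse(altitudes <= zk,
                lnp0 + (lnpk - lnp0) * (altitudes - z0) / (zk - z0),
                lnpk - upper_lnp_slope * (altitudes - zk))
  if (dip) {
    ramp <- pmax(0, (altitudes - (z1 - dip_width)) / dip_width)
    lnp <- lnp - dip_mag * ramp
  }
  build_profile(data.frame(altitude_km = altitudes, temperature_K = Tz,
                           ppH2O_mmHg = exp(lnp)))
}
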