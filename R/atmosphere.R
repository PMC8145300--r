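# Sulfuric-acid concentration of cloud droplets from temperature and water
# partial pressure, and altitude-resolved condition profiles.
#
# Droplets are assumed to be in equilibrium with atmospheric water vapor;
# the empirical vapor-pressure relation is inverted to give the acid
# concentration P (wt%) from ppH2O (mmHg) and T (K):
#
#   P = (ln(ppH2O) - 15.988 - 42.2/T) / (0.053346 - 84.03/T)
#
# Values above 100% denote fuming acid (oleum) and are returned as-is.

.acid_c1 <- 15.988
.acid_c2 <- 42.2
.acid_c3 <- 0.053346
.acid_c4 <- 84.03

#' Acid concentration in equilibrium with water vapor
#'
#' @param ppH2O partial pressure of water, millimeters of mercury (> 0)
#' @param T_K absolute temperature, kelvin (> 0)
#' @return acid concentration, percent by weight (may exceed 100: oleum)
#' @export
acid_wt_pct <- function(ppH2O, T_K) {
  stopifnot(all(ppH2O > 0), all(T_K > 0))
  den <- .acid_c3 - .acid_c4 / T_K
  if (any(abs(den) < 1e-8))
    stop("temperature at the singular point of the vapor-pressure relation")
  (log(ppH2O) - .acid_c1 - .acid_c2 / T_K) / den
}

#' Water vapor pressure over acid of a given concentration
#'
#' Algebraic inverse of [acid_wt_pct()]; round-trips exactly within
#' floating-point tolerance.
#'
#' @param P acid concentration, percent by weight
#' @param T_K absolute temperature, kelvin
#' @return ppH2O in mmHg
#' @export
ppH2O_forward <- function(P, T_K) {
  stopifnot(all(T_K > 0))
  exp(.acid_c1 + .acid_c2 / T_K + P * (.acid_c3 - .acid_c4 / T_K))
}

#' Build an altitude-resolved atmosphere profile
#'
#' Each level is annotated with the acid concentration in equilibrium with
#' its water vapor pressure.
#'
#' @param levels data.frame with columns `altitude_km`, `temperature_K`,
#'   `ppH2O_mmHg`; altitudes strictly increasing
#' @return an `atmosphere_profile` (the data.frame plus `acid_wt_pct`)
#' @export
build_profile <- function(levels) {
  need <- c("altitude_km", "temperature_K", "ppH2O_mmHg")
  if (!is.data.frame(levels) || !all(need %in% names(levels)))
    stop("levels must be a data.frame with columns ", paste(need, collapse = ","))
  if (!nrow(levels)) stop("empty level list")
  if (is.unsorted(levels$altitude_km, strictly = TRUE))
    stop("altitudes must be strictly increasing")
  levels$acid_wt_pct <- acid_wt_pct(levels$ppH2O_mmHg, levels$temperature_K)
  structure(levels, class = c("atmosphere_profile", "data.frame"))
}

#' Query a profile at an arbitrary altitude
#'
#' Temperature and ln(ppH2O) are interpolated linearly in altitude; the
#' acid concentration is recomputed from the interpolated inputs so that
#' the equilibrium relation holds exactly at every queried altitude.
#'
#' @param profile an `atmosphere_profile`
#' @param altitude_km altitude to query (within the profile span)
#' @return a [condition()] with extra fields `altitude_km` and `ppH2O_mmHg`
#' @export
profile_at <- function(profile, altitude_km) {
  z <- profile$altitude_km
  if (altitude_km < z[1] || altitude_km > z[length(z)])
    stop("altitude outside profile span")
  Tq <- stats::approx(z, profile$temperature_K, xout = altitude_km)$y
  pq <- exp(stats::approx(z, log(profile$ppH2O_mmHg), xout = altitude_km)$y)
  cond <- condition(acid_wt_pct(pq, Tq), Tq)
  cond$altitude_km <- altitude_km
  cond$ppH2O_mmHg <- pq
  cond
}

#' Read an atmosphere profile CSV
#' @param path CSV with header `altitude_km,temperature_K,ppH2O_mmHg`
#' @return an `atmosphere_profile`
#' @export
read_profile <- function(path) build_profile(utils::read.csv(path))

#' Write an atmosphere profile CSV (including derived acid percent)
#' @param profile an `atmosphere_profile`
#' @param path output CSV
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
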