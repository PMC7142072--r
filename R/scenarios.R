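#' Calibration scenario
#'
#' Bundles one calibration setting: a forcing series, an observation tunnel,
#' the compared trajectory variable, the initial bell diameter, and the
#' scenario's weight in the combined error. The laboratory growth scenario
#' additionally flags that its prey concentration is the searched quantity
#' `F_lab` (each random simulation overrides the forcing's prey column with
#' its drawn `F_lab`).
#'
#' @param name scenario label.
#' @param forcing a [forcing_series()].
#' @param tunnels a [tunnel_set()] (may be `NULL` until attached).
#' @param variable compared variable, `"bd"` or `"cm"`.
#' @param initial_bd initial bell diameter (cm).
#' @param weight weight in the combined error (equal weights by default).
#' @param uses_F_lab whether the prey concentration is the searched `F_lab`.
#' @return a `jelly_scenario` list.
#' @export
scenario <- function(name, forcing, tunnels = NULL, variable = c("bd", "cm"),
                     initial_bd = 4.5, weight = 1, uses_F_lab = FALSE) {
  variable <- match.arg(variable)
  check_positive(initial_bd, "initial_bd")
  if (!is.null(tunnels)) {
    if (min(tunnels$t_day) < min(forcing$t_day) ||
        max(tunnels$t_day) > max(forcing$t_day))
      stop("forcing does not span the tunnel times")
  }
  structure(list(name = name, forcing = forcing, tunnels = tunnels,
                 variable = variable, initial_bd = initial_bd,
                 weight = weight, uses_F_lab = isTRUE(uses_F_lab)),
            class = "jelly_scenario")
}

#' Laboratory degrowth scenario (starved, 18 degC)
#'
#' Constant 18 degC, zero prey, no deep-temperature averaging: the animal
#' only loses carbon, through respiration, excretion and reproduction, and
#' its bell diameter decreases quasi-exponentially. The starting bell
#' diameter is a surrogate value (the culturing experiments' exact starting
#' sizes are not published).
#'
#' @param duration experiment length (days).
#' @param initial_bd starting bell diameter (cm).
#' @param tunnels optional [tunnel_set()] on bell diameter.
#' @return a [scenario()].
#' @export
make_lab_degrowth <- function(duration = 30, initial_bd = 4.5,
                              tunnels = NULL) {
  fz <- forcing_series(0:duration, 18, NA, 0)
  scenario("lab_degrowth", fz, tunnels, "bd", initial_bd)
}

#' Laboratory growth scenario (fed, 18 degC)
#'
#' Constant 18 degC and constant prey concentration `F_lab`. Because "fed ad
#' libitum" does not pin down a concentration, `F_lab` is searched by the
#' SMCE alongside the model parameters: during candidate evaluation each
#' random simulation replaces the forcing's prey column with its drawn
#' `F_lab`. On long horizons the trajectory is sigmoid, plateauing where
#' assimilation balances respiration, excretion and reproduction.
#'
#' @param duration experiment length (days).
#' @param initial_bd starting bell diameter (cm); an ephyra-sized surrogate.
#' @param F_lab prey concentration used when simulating outside the SMCE
#'   (gC L^-1).
#' @param tunnels optional [tunnel_set()] on bell diameter.
#' @return a [scenario()].
#' @export
make_lab_growth <- function(duration = 30, initial_bd = 1.0, F_lab = 0.95e-5,
                            tunnels = NULL) {
  check_nonnegative(F_lab, "F_lab")
  fz <- forcing_series(0:duration, 18, NA, F_lab)
  scenario("lab_growth", fz, tunnels, "bd", initial_bd, uses_F_lab = TRUE)
}

#' In-situ annual scenario (climatology forcing)
#'
#' Wraps an annual climatology of sea-surface temperature and zooplankton
#' concentration. The deep-water temperature is fixed at 13 degC (the
#' Mediterranean bathypelagic), activating the day/night rate averaging that
#' represents the nycthemeral migration. Weekly climatologies are
#' interpolated linearly to daily resolution (observed values are preserved
#' exactly at the knots). Tunnels are built on adult bell diameter.
#'
#' @param climatology a [forcing_series()] covering one year.
#' @param tunnels optional [tunnel_set()] on bell diameter.
#' @param initial_bd starting bell diameter (cm); defaults to the smallest
#'   observed adult size.
#' @param T_deep bathypelagic temperature (degC).
#' @return a [scenario()].
#' @export
make_insitu <- function(climatology, tunnels = NULL, initial_bd = 2.1,
                        T_deep = 13) {
  t <- climatology$t_day
  if (max(t) - min(t) < 300)
    stop("climatology must cover (close to) one year")
  if (any(diff(t) > 1)) {   # e.g. weekly sampling: interpolate to daily
    td <- seq(min(t), max(t), by = 1)
    climatology <- forcing_series(
      td,
      approx(t, climatology$T_surface_C, td)$y,
      NA,
      approx(t, climatology$F_gC_per_L, td)$y)
  }
  climatology$T_deep_C <- T_deep
  scenario("insitu", climatology, tunnels, "bd", initial_bd)
}

#' Combined calibration error across scenarios
#'
#' Aggregates per-scenario tunnel violations into one error: per scenario,
#' the mean number of violated tunnel times per simulation is normalized by
#' the number of tunnel points and added to the mean normalized excursion,
#' then scenarios are combined with their weights. The per-point
#' normalization keeps a densely sampled condition (e.g. the 365-day in-situ
#' record vs. a 30-day experiment) from dominating the compromise.
#'
#' @param score per-scenario mean violated tunnel times per simulation.
#' @param dist per-scenario mean normalized excursion per simulation.
#' @param n_points per-scenario tunnel sizes.
#' @param weights per-scenario weights (equal by default).
#' @return a single non-negative number; 0 when every simulation matched
#'   every scenario.
#' @export
combined_error <- function(score, dist, n_points,
                           weights = rep(1, length(score))) {
  stopifnot(length(score) == length(dist), length(score) == length(n_points),
            length(score) == length(weights))
  sum(weights * (score / n_points + dist))
}
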