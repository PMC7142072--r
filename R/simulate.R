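#' Forcing time series
#'
#' Daily environmental forcing for the simulator: time (days), sea-surface
#' temperature, optional deep-water temperature (for the nycthemeral
#' vertical migration; rates are then averaged over both temperatures), and
#' prey carbon concentration.
#'
#' @param t time in days, strictly increasing.
#' @param T_surface surface temperature (degC).
#' @param T_deep deep temperature (degC), `NA` to disable averaging.
#' @param F prey concentration (gC L^-1), `>= 0`.
#' @return a `jelly_forcing` data frame with columns `t_day`,
#'   `T_surface_C`, `T_deep_C`, `F_gC_per_L`.
#' @examples
#' forcing_series(0:30, 18, NA, 0)       # starved laboratory conditions
#' @export
forcing_series <- function(t, T_surface, T_deep = NA, F) {
  n <- length(t)
  if (n < 1) stop("forcing must contain at least one record")
  if (any(diff(t) <= 0)) stop("forcing times must be strictly increasing")
  T_surface <- rep_len(T_surface, n)
  T_deep <- rep_len(T_deep, n)
  F <- rep_len(F, n)
  check_nonnegative(F, "F")
  out <- data.frame(t_day = as.numeric(t),
                    T_surface_C = as.numeric(T_surface),
                    T_deep_C = as.numeric(T_deep),
                    F_gC_per_L = as.numeric(F))
  class(out) <- c("jelly_forcing", "data.frame")
  out
}

#' Advance the state by one forward-Euler step
#'
#' Evaluates the flux breakdown at the current state and forcing record and
#' advances the carbon mass by `cm + dG * dt`. When the updated mass would
#' be non-positive, the organism has exhausted its carbon: the step returns
#' status `"exhausted"` and no new state, rather than silently clamping.
#'
#' @param state a list with `cm` (g C); `bd` and `wm` are recomputed.
#' @param record one row of a [forcing_series()] (or a list with
#'   `T_surface_C`, `T_deep_C`, `F_gC_per_L`).
#' @param params a [jelly_params()] object.
#' @param dt step length (days), `> 0`.
#' @return a list with `state` (cm, bd, wm after the step; `NULL` when
#'   exhausted), `fluxes` (the [flux_breakdown()] at the initial state) and
#'   `status` (`"ok"` or `"exhausted"`).
#' @export
step_jelly <- function(state, record, params, dt = 1) {
  stopifnot(dt > 0)
  temp <- record$T_surface_C
  if (!is.null(record$T_deep_C) && !is.na(record$T_deep_C))
    temp <- c(temp, record$T_deep_C)
  fx <- flux_breakdown(state$cm, temp, record$F_gC_per_L, params)
  cm_next <- state$cm + fx$dG * dt
  if (cm_next <= 0)
    return(list(state = NULL, fluxes = fx, status = "exhausted"))
  bd <- bd_from_cm(cm_next)
  list(state = list(cm = cm_next, bd = bd, wm = wm_from_bd(bd)),
       fluxes = fx, status = "ok")
}

#' Simulate a jellyfish trajectory
#'
#' Integrates the carbon budget with forward Euler along the forcing grid
#' (optionally sub-daily with `dt < 1`; forcing is held constant within a
#' day). The returned trajectory holds, per time point, the state (carbon
#' mass, bell diameter, wet mass) and the full flux breakdown evaluated at
#' that state, so consecutive rows satisfy `cm[i+1] = cm[i] + dG[i] * dt`.
#'
#' A trajectory whose carbon mass would become non-positive is truncated at
#' the last viable record and flagged with status `"exhausted"`; downstream
#' tunnel checks treat it as outside the tunnel from the truncation time
#' onward.
#'
#' @param initial_bd initial bell diameter (cm), `> 0`.
#' @param forcing a [forcing_series()].
#' @param params a [jelly_params()] object.
#' @param dt integration step in days (default 1, the native resolution of
#'   the daily rates). Must satisfy `0 < dt <= 1`.
#' @return a `jelly_trajectory` data frame with columns `t_day`, `cm_gC`,
#'   `bd_cm`, `wm_g`, `P`, `I`, `A`, `R_O2`, `R_C`, `Ex`, `Re`, `Eg`, `dG`;
#'   attributes `status` (`"ok"`/`"exhausted"`) and `n_valid`.
#' @examples
#' p <- jelly_params()
#' fz <- forcing_series(0:30, 18, NA, 0)
#' tr <- simulate_jelly(4.5, fz, p)      # starved degrowth
#' @export
simulate_jelly <- function(initial_bd, forcing, params, dt = 1) {
  check_positive(initial_bd, "initial_bd")
  stopifnot(inherits(forcing, "data.frame"), nrow(forcing) >= 1)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0 || dt > 1)
    stop("dt must be a single value in (0, 1]")
  if (dt == 1) {
    t <- forcing$t_day
    Ts <- forcing$T_surface_C
    Td <- forcing$T_deep_C
    F <- forcing$F_gC_per_L
  } else {
    t <- seq(min(forcing$t_day), max(forcing$t_day), by = dt)
    idx <- findInterval(t, forcing$t_day)
    Ts <- forcing$T_surface_C[idx]
    Td <- forcing$T_deep_C[idx]
    F <- forcing$F_gC_per_L[idx]
  }
  res <- sim_core_cpp(cm_from_bd(initial_bd), t, Ts,
                      if (is.null(Td)) rep(NA_real_, length(t)) else as.numeric(Td),
                      F, params_for_cpp(params))
  traj <- as.data.frame(res$traj)
  names(traj) <- c("t_day", "cm_gC", "bd_cm", "wm_g", "P", "I", "A",
                   "R_O2", "R_C", "Ex", "Re", "Eg", "dG")
  attr(traj, "status") <- res$status
  attr(traj, "n_valid") <- res$n_valid
  class(traj) <- c("jelly_trajectory", "data.frame")
  traj
}

#' @export
print.jelly_trajectory <- function(x, ...) {
  nv <- attr(x, "n_valid")
  if (is.null(nv)) nv <- nrow(x)
  status <- attr(x, "status")
  if (is.null(status)) status <- "ok"
  cat(sprintf("Jellyfish trajectory: %d records (%s)\n", nrow(x), status))
  cat(sprintf("  t = [%g, %g] d; bell diameter %0.3g -> %0.3g cm\n",
              x$t_day[1], x$t_day[nrow(x)], x$bd_cm[1], x$bd_cm[nv]))
  invisible(x)
}
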