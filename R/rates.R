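#' Ecophysiological process rates
#'
#' The seven daily carbon fluxes of the budget model, exposed individually.
#' All masses are in grams unless stated otherwise; temperatures in degC;
#' prey concentration `F` in gC L^-1.
#'
#' * `predation()` is the Michaelis-Menten-scaled predation term
#'   `P = p_max * cm^b_p * t_10p^T / (F + k_p)`; the ingestion rate is its
#'   product with prey concentration, `I = P * F` (gC d^-1), so `P`
#'   saturates ingestion at `p_max * cm^b_p * t_10p^T` for abundant prey.
#' * `assimilation()` applies the Holling-type factor
#'   `A = I * (1 - a_max * F / (F + k_a))`: the assimilated fraction
#'   decreases with increasing prey concentration, down to `1 - a_max` at
#'   saturation.
#' * `respiration()` evaluates `R_O2 = R_o * mass^b_r * t_10r^T`
#'   (umol O2 d^-1) on the configured mass basis (wet mass by default) and
#'   converts it to carbon with the oxygen-to-energy (`beta`) and
#'   energy-to-carbon (`alpha`) factors: `R_C = R_O2 * beta * alpha`.
#' * `excretion()` scales respired carbon: `Ex = R_C * c_e`.
#' * `reproduction()` releases egg + mucus carbon
#'   `Re = (a_re * size^b_re) * W_e * c_re * spn` once the animal is
#'   sexually mature (bell diameter at or above `maturity_bd`), zero below.
#'
#' @param cm carbon mass (g C).
#' @param temp temperature (degC); may be a vector of two (surface, deep)
#'   whose rates are averaged, mirroring the nycthemeral migration.
#' @param F prey concentration (gC L^-1), `>= 0`.
#' @param params a [jelly_params()] object.
#' @param P predation term as returned by `predation()`.
#' @param I ingestion rate (gC d^-1).
#' @param R_C respired carbon (gC d^-1).
#' @param c_e excretion scalar.
#' @param bd bell diameter (cm); computed from `cm` when missing.
#' @return a numeric rate; `respiration()` returns a list with `R_O2`
#'   (umol O2 d^-1) and `R_C` (gC d^-1).
#' @examples
#' p <- jelly_params()
#' P <- predation(cm_from_bd(4), 18, 9e-6, p)
#' I <- ingestion(P, 9e-6)
#' assimilation(I, 9e-6, p)
#' respiration(cm_from_bd(4), 18, p)
#' @name rates
NULL

#' @rdname rates
#' @export
predation <- function(cm, temp, F, params) {
  check_positive(cm, "cm")
  check_nonnegative(F, "F")
  if (all(F + params$k_p == 0)) stop("F + k_p must be > 0")
  t_avg <- mean(params$t_10p^temp)
  params$p_max * cm^params$b_p * t_avg / (F + params$k_p)
}

#' @rdname rates
#' @export
ingestion <- function(P, F) {
  check_nonnegative(P, "P")
  check_nonnegative(F, "F")
  P * F
}

#' @rdname rates
#' @export
assimilation <- function(I, F, params) {
  check_nonnegative(I, "I")
  check_nonnegative(F, "F")
  I * (1 - params$a_max * F / (F + params$k_a))
}

#' @rdname rates
#' @export
respiration <- function(cm, temp, params) {
  check_positive(cm, "cm")
  mass <- if (params$respiration_mass_basis == "wm") {
    wm_from_bd(bd_from_cm(cm))
  } else {
    cm
  }
  R_O2 <- params$R_o * mass^params$b_r * mean(params$t_10r^temp)
  list(R_O2 = R_O2, R_C = R_O2 * params$beta * params$alpha)
}

#' @rdname rates
#' @export
excretion <- function(R_C, c_e) {
  check_nonnegative(R_C, "R_C")
  check_nonnegative(c_e, "c_e")
  R_C * c_e
}

#' @rdname rates
#' @export
reproduction <- function(cm, params, bd = bd_from_cm(cm)) {
  check_positive(cm, "cm")
  if (bd < params$maturity_bd) return(0)
  size <- switch(params$reproduction_size_basis,
                 bd_cm = bd, cm_mg = cm * 1000, cm_g = cm)
  (params$a_re * size^params$b_re) * params$W_e * params$c_re * params$spn
}

#' Full per-day flux breakdown at a given state
#'
#' Evaluates every process rate at carbon mass `cm`, assembling the carbon
#' bookkeeping `Eg = I - A` (egestion is ingested-but-unassimilated carbon,
#' released as mucus) and the net growth `dG = A - (R_C + Ex + Re)`. With a
#' surface and a deep temperature, each temperature-dependent rate is
#' evaluated at both and averaged with equal weight.
#'
#' @inheritParams rates
#' @return a named list: `P`, `I`, `A`, `R_O2`, `R_C`, `Ex`, `Re`, `Eg`,
#'   `dG` (all daily rates).
#' @export
flux_breakdown <- function(cm, temp, F, params) {
  stopifnot(length(temp) %in% 1:2, length(F) == 1, length(cm) == 1)
  P <- mean(vapply(temp, function(T) predation(cm, T, F, params), 0))
  I <- ingestion(P, F)
  A <- assimilation(I, F, params)
  r <- lapply(temp, function(T) respiration(cm, T, params))
  R_O2 <- mean(vapply(r, `[[`, 0, "R_O2"))
  R_C <- mean(vapply(r, `[[`, 0, "R_C"))
  Ex <- excretion(R_C, params$c_e)
  Re <- reproduction(cm, params)
  Eg <- I - A
  list(P = P, I = I, A = A, R_O2 = R_O2, R_C = R_C,
       Ex = Ex, Re = Re, Eg = Eg, dG = A - (R_C + Ex + Re))
}
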