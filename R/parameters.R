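#' Couple the maximum predation rate to the predation half-saturation
#'
#' The maximum net feeding rate of a 1 g C individual at 0 degC and the
#' predation half-saturation constant are not independent: the literature
#' feeding observations behind the predation allometry are assumed to have
#' been made at food saturation, i.e. at a reference prey concentration
#' `F_sat` taken as twice the maximum in-situ concentration. Under that
#' assumption the Michaelis-Menten predation term pins
#' `p_max = 0.1399 * (1 + k_p / F_sat)`, so a candidate `k_p` fixes `p_max`.
#'
#' @param k_p predation half-saturation constant (gC L^-1), `>= 0`.
#' @param F_sat food-saturation reference concentration (gC L^-1), `> 0`.
#' @return maximum predation rate (gC ind^-1 d^-1).
#' @examples
#' p_max_from_kp(0)              # 0.1399
#' p_max_from_kp(1.9e-4)         # the laboratory best-fit k_p
#' @export
p_max_from_kp <- function(k_p, F_sat = 1.2e-4) {
  stopifnot(is.numeric(k_p), is.numeric(F_sat))
  if (any(k_p < 0)) stop("k_p must be >= 0")
  if (any(F_sat <= 0)) stop("F_sat must be > 0")
  0.1399 * (1 + k_p / F_sat)
}

#' Ecophysiological parameter set
#'
#' Bundles the 17 parameters of the carbon-budget model. Eleven are fixed
#' from published experiments (predation and respiration allometries, energy
#' and oxygen conversion factors, egg allometry and egg carbon mass); six are
#' the quantities the statistical model checking engine searches for
#' (`k_p`, `a_max`, `k_a`, `c_re`, `spn`, `c_e`). The searched parameters
#' default to the laboratory best-fit central values so that a plain
#' `jelly_params()` simulates a calibrated animal.
#'
#' `p_max` is derived from `k_p` through [p_max_from_kp()] unless supplied
#' explicitly. A single `t_10` (tenth root of the Q10 coefficient) is shared
#' by predation and respiration by default; per-process overrides are
#' available because the two rates were calibrated from different datasets.
#'
#' Two unit-basis switches document genuinely ambiguous points of the model:
#' * `respiration_mass_basis`: the respiration allometry coefficient `R_o`
#'   is defined per 1 g wet mass, so the default basis is wet mass (`"wm"`);
#'   `"cm"` evaluates the same law on carbon mass in g.
#' * `reproduction_size_basis`: the egg-production power law is evaluated on
#'   bell diameter in cm by default (`"bd_cm"`), which yields hundreds to
#'   thousands of eggs per spawn for adults and a growth plateau inside the
#'   observed 2.1-21 cm size range. The alternative carbon-mass readings
#'   (`"cm_mg"`, `"cm_g"`) are provided but produce egg numbers that are
#'   orders of magnitude too high, resp. too low, for a viable adult (see
#'   the methods vignette).
#'
#' @param k_p predation half-saturation (gC L^-1).
#' @param a_max maximum assimilated fraction (dimensionless, in \[0, 1\]).
#' @param k_a assimilation half-saturation (gC L^-1).
#' @param c_re mucus proportion multiplier on egg carbon (dimensionless).
#' @param spn spawning rate (d^-1).
#' @param c_e excretion scalar on respiration (dimensionless).
#' @param b_p predation allometric exponent.
#' @param R_o respiration rate of a 1 g wet-mass individual at 0 degC
#'   (umol O2 d^-1).
#' @param b_r respiration allometric exponent.
#' @param t_10 tenth root of the Q10 coefficient (shared default).
#' @param t_10p,t_10r optional per-process overrides of `t_10`.
#' @param alpha energy-to-carbon conversion (gC J^-1).
#' @param beta oxygen-to-energy conversion (J umolO2^-1).
#' @param a_re,b_re egg-production power-law coefficient and exponent.
#' @param W_e egg carbon mass (gC egg^-1).
#' @param F_sat food-saturation reference (gC L^-1) used to derive `p_max`.
#' @param maturity_bd bell diameter at sexual maturity (cm); reproduction is
#'   zero strictly below it.
#' @param p_max maximum predation rate; derived from `k_p` when `NULL`.
#' @param respiration_mass_basis `"wm"` (default) or `"cm"`.
#' @param reproduction_size_basis `"bd_cm"` (default), `"cm_mg"` or `"cm_g"`.
#' @return an object of class `jelly_params` (a named list).
#' @examples
#' p <- jelly_params()
#' p$p_max                      # derived from k_p
#' jelly_params(c_e = 0.5)$c_e
#' @export
jelly_params <- function(k_p = 1.9e-4, a_max = 0.8, k_a = 5e-5, c_re = 2.7,
                         spn = 0.7, c_e = 0,
                         b_p = 0.8856, R_o = 2.80, b_r = 0.934,
                         t_10 = 1.066, t_10p = NULL, t_10r = NULL,
                         alpha = 2.28e-5, beta = 0.447,
                         a_re = 0.07, b_re = 4.66, W_e = 1.52e-6,
                         F_sat = 1.2e-4, maturity_bd = 4,
                         p_max = NULL,
                         respiration_mass_basis = c("wm", "cm"),
                         reproduction_size_basis = c("bd_cm", "cm_mg", "cm_g")) {
  respiration_mass_basis <- match.arg(respiration_mass_basis)
  reproduction_size_basis <- match.arg(reproduction_size_basis)
  if (is.null(p_max)) p_max <- p_max_from_kp(k_p, F_sat)
  if (is.null(t_10p)) t_10p <- t_10
  if (is.null(t_10r)) t_10r <- t_10
  p <- list(p_max = p_max, b_p = b_p, k_p = k_p,
            R_o = R_o, b_r = b_r,
            t_10 = t_10, t_10p = t_10p, t_10r = t_10r,
            alpha = alpha, beta = beta,
            a_re = a_re, b_re = b_re, W_e = W_e,
            c_re = c_re, spn = spn,
            a_max = a_max, k_a = k_a, c_e = c_e,
            F_sat = F_sat, maturity_bd = maturity_bd,
            respiration_mass_basis = respiration_mass_basis,
            reproduction_size_basis = reproduction_size_basis)
  validate_jelly_params(p)
  class(p) <- "jelly_params"
  p
}

validate_jelly_params <- function(p) {
  num <- c("p_max", "b_p", "k_p", "R_o", "b_r", "t_10", "t_10p", "t_10r",
           "alpha", "beta", "a_re", "b_re", "W_e", "c_re", "spn",
           "a_max", "k_a", "c_e", "F_sat", "maturity_bd")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
    if (v < 0) stop("parameter '", nm, "' must be >= 0")
  }
  if (p$a_max > 1) stop("a_max must lie in [0, 1]")
  if (p$t_10 <= 1 || p$t_10p <= 1 || p$t_10r <= 1)
    stop("t_10 must exceed 1 (rates increase with temperature)")
  if (p$maturity_bd <= 0) stop("maturity_bd must be > 0")
  invisible(p)
}

#' Names of the searched (free) parameters
#'
#' The six model parameters inferred by the SMCE, plus the laboratory prey
#' concentration `F_lab`, which is searched alongside them because "fed ad
#' libitum" does not pin down a concentration.
#'
#' @return character vector of length 7.
#' @export
searched_parameter_names <- function() {
  c("k_p", "a_max", "k_a", "c_re", "spn", "c_e", "F_lab")
}

#' Replace searched parameters inside a parameter set
#'
#' Returns a copy of `params` with the searched entries overwritten by the
#' values in `draw` (a named vector or one-row data frame) and `p_max`
#' re-derived from the new `k_p`. `F_lab`, if present in `draw`, is carried
#' through as an attribute for scenario construction rather than a model
#' parameter.
#'
#' @param params a [jelly_params()] object.
#' @param draw named numeric vector with any of the searched names.
#' @return a `jelly_params` object.
#' @export
set_searched <- function(params, draw) {
  stopifnot(inherits(params, "jelly_params"))
  draw <- unlist(draw)
  for (nm in intersect(names(draw), c("k_p", "a_max", "k_a", "c_re", "spn", "c_e")))
    params[[nm]] <- unname(draw[[nm]])
  params$p_max <- p_max_from_kp(params$k_p, params$F_sat)
  validate_jelly_params(params)
  if ("F_lab" %in% names(draw)) attr(params, "F_lab") <- unname(draw[["F_lab"]])
  params
}

#' @export
print.jelly_params <- function(x, ...) {
  cat("Jellyfish carbon-budget parameter set\n")
  cat(sprintf("  predation:     p_max = %.4g (derived), b_p = %.4g, k_p = %.3g\n",
              x$p_max, x$b_p, x$k_p))
  cat(sprintf("  respiration:   R_o = %.3g umolO2/d per g %s, b_r = %.4g\n",
              x$R_o, toupper(x$respiration_mass_basis), x$b_r))
  cat(sprintf("  assimilation:  a_max = %.3g, k_a = %.3g\n", x$a_max, x$k_a))
  cat(sprintf("  reproduction:  a_re = %.3g, b_re = %.3g on %s, W_e = %.3g, c_re = %.3g, spn = %.3g\n",
              x$a_re, x$b_re, x$reproduction_size_basis, x$W_e, x$c_re, x$spn))
  cat(sprintf("  excretion:     c_e = %.3g\n", x$c_e))
  cat(sprintf("  temperature:   t_10 = %.4g (Q10 = %.3g)\n", x$t_10, x$t_10^10))
  cat(sprintf("  maturity at bell diameter >= %.3g cm\n", x$maturity_bd))
  invisible(x)
}

# integer codes handed to the compiled kernel
params_for_cpp <- function(p) {
  list(p_max = p$p_max, b_p = p$b_p, k_p = p$k_p,
       R_o = p$R_o, b_r = p$b_r, t_10p = p$t_10p, t_10r = p$t_10r,
       alpha = p$alpha, beta = p$beta,
       a_re = p$a_re, b_re = p$b_re, W_e = p$W_e,
       c_re = p$c_re, spn = p$spn,
       a_max = p$a_max, k_a = p$k_a, c_e = p$c_e,
       maturity_bd = p$maturity_bd,
       resp_basis = if (p$respiration_mass_basis == "wm") 0L else 1L,
       repro_basis = match(p$reproduction_size_basis,
                           c("bd_cm", "cm_mg", "cm_g")) - 1L)
}
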