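#' Morphometric conversions for Pelagia noctiluca
#'
#' Allometric conversions between bell diameter over lappets (BD, cm), wet
#' mass (WM, g) and carbon mass (CM): `WM = 0.075 * BD^2.993` and
#' `CM = 0.26 * BD^3.017` with CM in mg. [cm_from_bd()] reports carbon mass
#' in grams; [bd_from_cm()] is the closed-form inverse. Across the observed
#' size range the carbon mass is close to 0.36% of the wet mass.
#'
#' @param bd bell diameter over lappets (cm), `> 0`.
#' @param cm carbon mass (g C), `> 0`.
#' @return [wm_from_bd()]: wet mass (g); [cm_from_bd()]: carbon mass (g C);
#'   [bd_from_cm()]: bell diameter (cm); [cm_wm_ratio()]: dimensionless
#'   carbon-to-wet-mass ratio.
#' @examples
#' wm_from_bd(10)
#' cm_from_bd(10)
#' bd_from_cm(cm_from_bd(4))      # 4
#' 100 * cm_wm_ratio(6.6)         # ~0.36 (percent)
#' @name morphometry
NULL

#' @rdname morphometry
#' @export
wm_from_bd <- function(bd) {
  check_positive(bd, "bd")
  0.075 * bd^2.993
}

#' @rdname morphometry
#' @export
cm_from_bd <- function(bd) {
  check_positive(bd, "bd")
  0.26 * bd^3.017 / 1000
}

#' @rdname morphometry
#' @export
bd_from_cm <- function(cm) {
  check_positive(cm, "cm")
  (cm * 1000 / 0.26)^(1 / 3.017)
}

#' @rdname morphometry
#' @export
cm_wm_ratio <- function(bd) {
  cm_from_bd(bd) / wm_from_bd(bd)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("'", name, "' must be positive and finite", call. = FALSE)
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop("'", name, "' must be non-negative and finite", call. = FALSE)
  invisible(x)
}
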