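#' Carbon loss of sinking mucus
#'
#' Fraction of a mucus particle's carbon remineralized while sinking from
#' the surface to depth `z` at speed `w` while decaying at rate `k`. The
#' default form is the exponential attenuation `1 - exp(-k * z / w)`; the
#' `"linear"` variant `k * z / w` (the first-order expansion) is also
#' provided. Both evaluate to about 1% at the measured median sinking speed
#' (751 m d^-1), remineralization rate (0.034 d^-1) and a 200 m horizon.
#'
#' @param w sinking speed (m d^-1), `> 0`.
#' @param k remineralization rate (d^-1), `>= 0`.
#' @param z depth horizon (m), `>= 0`.
#' @param form `"exponential"` (default) or `"linear"`.
#' @return fraction lost, in `[0, 1]` (the linear form can exceed 1 for
#'   extreme arguments and is capped at 1).
#' @examples
#' round(100 * loss_fraction(751, 0.034, 200))   # 1 (%)
#' @export
loss_fraction <- function(w = 751, k = 0.034, z = 200,
                          form = c("exponential", "linear")) {
  form <- match.arg(form)
  check_positive(w, "w")
  check_nonnegative(k, "k")
  check_nonnegative(z, "z")
  x <- k * z / w
  if (form == "exponential") 1 - exp(-x) else pmin(1, x)
}

#' Areal POC export from jellyfish egestion
#'
#' Converts a per-individual egestion rate into an areal particulate
#' organic carbon flux at depth: the egested mucus sinks at speed `w`,
#' loses [loss_fraction()] of its carbon to remineralization on the way to
#' depth `z`, and is scaled by the areal abundance of individuals. Jointly
#' linear in egestion and abundance.
#'
#' @param Eg per-individual egestion (gC ind^-1 d^-1).
#' @param abundance areal abundance (ind m^-2).
#' @param w,k,z mucus sinking speed, remineralization rate and depth
#'   horizon, as in [loss_fraction()].
#' @param form attenuation form.
#' @return flux at depth (mgC m^-2 d^-1).
#' @export
areal_export <- function(Eg, abundance, w = 751, k = 0.034, z = 200,
                         form = c("exponential", "linear")) {
  check_nonnegative(Eg, "Eg")
  check_nonnegative(abundance, "abundance")
  Eg * abundance * (1 - loss_fraction(w, k, z, form)) * 1000
}

#' Jellyfish share of the total POC flux
#'
#' Expresses a jellyfish-derived POC flux as a percentage of a reference
#' total POC flux at the same depth (e.g. a sediment-trap climatology).
#'
#' @param flux_jelly jellyfish POC flux (mgC m^-2 d^-1).
#' @param reference total POC flux (mgC m^-2 d^-1), `> 0`.
#' @return percentage.
#' @examples
#' percent_poc(0.2, 13.55)
#' @export
percent_poc <- function(flux_jelly, reference) {
  check_nonnegative(flux_jelly, "flux_jelly")
  check_positive(reference, "reference")
  100 * flux_jelly / reference
}

#' Areal abundance summary
#'
#' Quantile summary of areal jellyfish abundance used to bracket export
#' estimates. Defaults are the 2013 ship-transect summary for the Ligurian
#' Sea: median 0.018 ind m^-2, quartiles 0.003 and 0.1, range 0 to 3.45.
#'
#' @param median,q1,q3,min,max abundance quantiles (ind m^-2), ordered
#'   `min <= q1 <= median <= q3 <= max`.
#' @return an `abundance_stats` list.
#' @export
abundance_stats <- function(median = 0.018, q1 = 0.003, q3 = 0.1,
                            min = 0, max = 3.45) {
  if (!(min <= q1 && q1 <= median && median <= q3 && q3 <= max))
    stop("abundance quantiles must be ordered min <= q1 <= median <= q3 <= max")
  structure(list(min = min, q1 = q1, median = median, q3 = q3, max = max),
            class = "abundance_stats")
}

#' Monthly jellyfish POC contribution table
#'
#' Aggregates a simulated trajectory's egestion flux by month, converts it
#' to areal export at depth for each abundance quantile, and expresses it
#' as a percentage of a monthly reference POC flux.
#'
#' @param trajectory a [simulate_jelly()] trajectory spanning (up to) one
#'   year, with `t_day` counted from day 0.
#' @param abundance an [abundance_stats()].
#' @param poc_reference data frame with columns `month` (1-12) and `poc`
#'   (total POC flux, mgC m^-2 d^-1), or `NULL` to report fluxes only.
#' @param w,k,z mucus sinking and remineralization parameters.
#' @return data frame with one row per month: mean egestion, export flux
#'   per abundance quantile (`flux_*`, mgC m^-2 d^-1) and, when a reference
#'   is given, the percentage columns (`pct_*`).
#' @export
export_table <- function(trajectory, abundance = abundance_stats(),
                         poc_reference = NULL, w = 751, k = 0.034, z = 200) {
  nv <- attr(trajectory, "n_valid")
  if (is.null(nv)) nv <- nrow(trajectory)
  tr <- trajectory[seq_len(nv), ]
  month <- pmin(12L, floor(tr$t_day %% 365 / 365 * 12) + 1L)
  eg <- tapply(tr$Eg, month, mean)
  out <- data.frame(month = as.integer(names(eg)), Eg_gC_per_ind_day = as.numeric(eg))
  for (q in c("q1", "median", "q3")) {
    out[[paste0("flux_", q)]] <-
      areal_export(out$Eg_gC_per_ind_day, abundance[[q]], w, k, z)
  }
  if (!is.null(poc_reference)) {
    stopifnot(all(c("month", "poc") %in% names(poc_reference)))
    ref <- poc_reference$poc[match(out$month, poc_reference$month)]
    ok <- !is.na(ref)
    for (q in c("q1", "median", "q3")) {
      pct <- rep(NA_real_, nrow(out))
      pct[ok] <- percent_poc(out[[paste0("flux_", q)]][ok], ref[ok])
      out[[paste0("pct_", q)]] <- pct
    }
  }
  rownames(out) <- NULL
  out
}
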