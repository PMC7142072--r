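#' Search vector for one parameter
#'
#' A bracket `[lo : step : hi]` describing the grid of candidate central
#' values for one searched parameter. Values are index-generated
#' (`lo + (0:(n-1)) * step`) to avoid floating-point drift; `hi` is an upper
#' bound and need not be hit exactly (e.g. `[3e-5 : 2e-5 : 2e-4]` ends at
#' 1.9e-4).
#'
#' @param lo,step,hi lower bound, resolution and upper bound in the
#'   parameter's native units; `step > 0`, `hi >= lo`.
#' @return a `search_vector` object.
#' @examples
#' sv <- search_vector(0.4, 0.1, 1)
#' sv_values(sv)            # 0.4 0.5 ... 1.0
#' sv_count(sv)             # 7
#' @export
search_vector <- function(lo, step, hi) {
  stopifnot(is.numeric(lo), is.numeric(step), is.numeric(hi),
            length(lo) == 1, length(step) == 1, length(hi) == 1)
  if (step <= 0) stop("step must be > 0")
  if (hi < lo) stop("hi must be >= lo")
  structure(list(lo = lo, step = step, hi = hi), class = "search_vector")
}

#' @rdname search_vector
#' @param sv a `search_vector`.
#' @export
sv_count <- function(sv) {
  as.integer(floor((sv$hi - sv$lo) / sv$step + 1e-9)) + 1L
}

#' @rdname search_vector
#' @export
sv_values <- function(sv) {
  sv$lo + (seq_len(sv_count(sv)) - 1L) * sv$step
}

#' @export
print.search_vector <- function(x, ...) {
  cat(sprintf("[%g : %g : %g] (%d values)\n", x$lo, x$step, x$hi, sv_count(x)))
  invisible(x)
}

#' Published search brackets for the unknown parameters
#'
#' The grid brackets over which the six unknown ecophysiological parameters
#' and the laboratory prey concentration are searched: `k_p`
#' \[3e-5 : 2e-5 : 2e-4\], `a_max` \[0.5 : 0.1 : 1\], `k_a`
#' \[1.5e-5 : 0.5e-5 : 5e-5\], `c_re` \[1 : 0.1 : 3\], `spn`
#' \[0.4 : 0.1 : 1\], `c_e` \[0 : 0.2 : 2\] and `F_lab`
#' \[0.7e-5 : 0.1e-5 : 1.2e-5\]. Their Cartesian product spans 4,191,264
#' candidate vectors.
#'
#' @return named list of [search_vector()]s.
#' @export
table1_search_vectors <- function() {
  list(k_p   = search_vector(3e-5, 2e-5, 2e-4),
       a_max = search_vector(0.5, 0.1, 1),
       k_a   = search_vector(1.5e-5, 0.5e-5, 5e-5),
       c_re  = search_vector(1, 0.1, 3),
       spn   = search_vector(0.4, 0.1, 1),
       c_e   = search_vector(0, 0.2, 2),
       F_lab = search_vector(0.7e-5, 0.1e-5, 1.2e-5))
}

#' Default pseudo standard deviations of the searched parameters
#'
#' Half-widths of the uniform uncertainty interval wrapped around each
#' candidate's central value before simulation: `spn`, `a_max`, `c_re`
#' +/- 0.05; `k_a` +/- 5e-6; `k_p` +/- 1e-5; `c_e` +/- 0.025. `F_lab` uses
#' half its grid resolution (+/- 5e-7), consistent with the pattern of the
#' other brackets.
#'
#' @return named numeric vector.
#' @export
default_pseudo_std <- function() {
  c(k_p = 1e-5, a_max = 0.05, k_a = 5e-6, c_re = 0.05,
    spn = 0.05, c_e = 0.025, F_lab = 5e-7)
}

#' Size of the candidate search space
#'
#' Product of the per-parameter grid counts; computed without materializing
#' the Cartesian product.
#'
#' @param vectors named list of [search_vector()]s.
#' @return the number of candidate vectors (double, to allow large grids).
#' @examples
#' space_size(table1_search_vectors())    # 4191264
#' @export
space_size <- function(vectors) {
  stopifnot(length(vectors) >= 1)
  prod(vapply(vectors, sv_count, 0L))
}

#' Enumerate the candidate search space
#'
#' Materializes the lexicographic Cartesian product of the search vectors:
#' the first parameter varies slowest, the last fastest. Each row is one
#' candidate vector of central values; `candidate_index` identifies it
#' stably (it also seeds the per-candidate random stream during
#' evaluation, making results independent of evaluation order).
#'
#' @param vectors named list of [search_vector()]s.
#' @param max_size guard against accidentally materializing the full
#'   multi-million-candidate grid; raise it deliberately if that is really
#'   intended.
#' @return data frame with one column per parameter plus `candidate_index`.
#' @examples
#' enumerate_space(list(a = search_vector(0, 1, 1), b = search_vector(0, 1, 2)))
#' @export
enumerate_space <- function(vectors, max_size = 1e6) {
  n <- space_size(vectors)
  if (n > max_size)
    stop("search space holds ", format(n, big.mark = ","),
         " candidates; raise max_size to materialize it")
  vals <- lapply(vectors, sv_values)
  grid <- expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(vals)), drop = FALSE]
  names(grid) <- names(vectors)
  # expand.grid varies the first factor fastest; after reversal the last
  # named parameter is fastest, i.e. lexicographic order
  grid$candidate_index <- seq_len(nrow(grid))
  rownames(grid) <- NULL
  grid
}

#' Reduced search grid centred on a reference vector
#'
#' Builds a 3-value bracket per searched parameter (centre and one grid
#' resolution either side, clamped at zero and at 1 for `a_max`), using the
#' published bracket resolutions. Used by the synthetic parameter-recovery
#' experiment, where the ground truth must lie on the grid.
#'
#' @param centre named numeric vector of central values (defaults to the
#'   laboratory best-fit central values with `F_lab = 9e-6`).
#' @return named list of [search_vector()]s, 3 values each.
#' @export
reduced_search_vectors <- function(centre = c(k_p = 1.9e-4, a_max = 0.8,
                                              k_a = 5e-5, c_re = 2.7,
                                              spn = 0.7, c_e = 0,
                                              F_lab = 9e-6)) {
  steps <- c(k_p = 2e-5, a_max = 0.1, k_a = 0.5e-5, c_re = 0.1,
             spn = 0.1, c_e = 0.2, F_lab = 0.1e-5)
  caps <- c(k_p = Inf, a_max = 1, k_a = Inf, c_re = Inf,
            spn = Inf, c_e = Inf, F_lab = Inf)
  out <- list()
  for (nm in names(steps)) {
    ctr <- centre[[nm]]
    st <- steps[[nm]]
    lo <- ctr - st
    if (lo < 0) lo <- 0
    hi <- lo + 2 * st
    if (hi > caps[[nm]]) {
      hi <- caps[[nm]]
      lo <- hi - 2 * st
    }
    out[[nm]] <- search_vector(lo, st, hi)
  }
  out
}
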