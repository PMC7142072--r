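#' Statistical-model-checking configuration
#'
#' Run settings of the match-probability estimation: number of Monte Carlo
#' simulations per candidate, the estimation precision `epsilon` (the true
#' match probability lies within `theta_hat +/- epsilon`), the error rate
#' `delta` used for both SPRT error bounds, and the retention threshold
#' `gamma` (candidates with estimated match probability above it are kept).
#' Defaults are 500 simulations, 5% precision, 1% error and a 70% match
#' threshold.
#'
#' Note that the number of simulations actually required by the
#' Chernoff-Hoeffding bound for precision `epsilon` at confidence
#' `1 - delta` is [ch_required_n()]; with the defaults it is 1060, more than
#' the configured 500. The default reproduces the published run
#' configuration; pass `n_sims = ch_required_n(...)` for the bound-backed
#' sample size.
#'
#' @param n_sims Monte Carlo simulations per candidate.
#' @param epsilon estimation precision, in (0, 1).
#' @param delta error rate for estimation and SPRT, in (0, 1).
#' @param gamma match-probability retention threshold, in (0, 1); the SPRT
#'   indifference region is `[gamma - epsilon, gamma + epsilon]`, which must
#'   stay inside (0, 1).
#' @param use_sprt prune candidates early with the SPRT (the SPRT only ever
#'   rejects; estimation always runs to `n_sims` for surviving candidates).
#' @return an `smc_config` list.
#' @export
smc_config <- function(n_sims = 500, epsilon = 0.05, delta = 0.01,
                       gamma = 0.70, use_sprt = TRUE) {
  stopifnot(n_sims >= 1, epsilon > 0, epsilon < 1, delta > 0, delta < 1,
            gamma > 0, gamma < 1, gamma - epsilon > 0, gamma + epsilon < 1)
  structure(list(n_sims = as.integer(n_sims), epsilon = epsilon,
                 delta = delta, gamma = gamma, use_sprt = isTRUE(use_sprt)),
            class = "smc_config")
}

#' Chernoff-Hoeffding sample size for probability estimation
#'
#' Smallest number of Bernoulli draws guaranteeing that the empirical
#' frequency deviates from the true probability by more than `epsilon` with
#' probability at most `delta`: `n >= log(2/delta) / (2 * epsilon^2)`.
#'
#' @param epsilon precision.
#' @param delta error rate.
#' @return integer sample size.
#' @examples
#' ch_required_n(0.05, 0.01)   # 1060
#' @export
ch_required_n <- function(epsilon = 0.05, delta = 0.01) {
  stopifnot(epsilon > 0, epsilon < 1, delta > 0, delta < 1)
  as.integer(ceiling(log(2 / delta) / (2 * epsilon^2)))
}

#' Observation tunnel
#'
#' A time-indexed acceptance band on one trajectory variable: a simulation
#' matches the observations when the variable lies within `[lower, upper]`
#' at every tunnel time. Tunnels are typically built from replicate
#' observations as mean +/- k standard deviations.
#'
#' @param t observation times (days), sorted.
#' @param lower,upper band bounds, `lower <= upper` everywhere, in the units
#'   of `variable`.
#' @param variable `"bd"` (bell diameter, cm) or `"cm"` (carbon mass, g C).
#' @return a `jelly_tunnel` data frame with attribute `variable`.
#' @export
tunnel_set <- function(t, lower, upper, variable = c("bd", "cm")) {
  variable <- match.arg(variable)
  stopifnot(length(t) == length(lower), length(t) == length(upper))
  if (is.unsorted(t)) stop("tunnel times must be sorted")
  if (any(lower > upper)) stop("tunnel lower bound exceeds upper bound")
  out <- data.frame(t_day = as.numeric(t), lower = as.numeric(lower),
                    upper = as.numeric(upper))
  attr(out, "variable") <- variable
  class(out) <- c("jelly_tunnel", "data.frame")
  out
}

#' Check a trajectory against an observation tunnel
#'
#' Interpolates the compared variable linearly between simulated records at
#' every tunnel time and tests whether it lies inside the band everywhere.
#' The distance is the mean over tunnel times of the excursion beyond the
#' nearest bound, normalized by the local tunnel half-width (raw excursion
#' where the band is degenerate, i.e. `lower == upper`); it is 0 for a
#' matching trajectory. An exhausted (truncated) trajectory counts as
#' outside from the truncation time onward (the variable is taken as 0: no
#' organism left).
#'
#' @param trajectory a [simulate_jelly()] trajectory.
#' @param tunnel a [tunnel_set()].
#' @return list with `inside` (logical), `dist`, `n_outside` (tunnel times
#'   violated), `n_points`.
#' @export
check_tunnel <- function(trajectory, tunnel) {
  var_col <- if (attr(tunnel, "variable") == "bd") "bd_cm" else "cm_gC"
  nv <- attr(trajectory, "n_valid")
  if (is.null(nv)) nv <- nrow(trajectory)
  tt <- trajectory$t_day[seq_len(nv)]
  vv <- trajectory[[var_col]][seq_len(nv)]
  if (min(tunnel$t_day) < min(tt))
    stop("trajectory does not span the earliest tunnel time")
  v <- if (nv == 1) {
    ifelse(tunnel$t_day <= tt, vv, 0)
  } else {
    out <- approx(tt, vv, xout = tunnel$t_day, rule = 1)$y
    out[is.na(out)] <- 0   # beyond truncation: organism gone
    out
  }
  exc <- pmax(0, tunnel$lower - v, v - tunnel$upper)
  half <- (tunnel$upper - tunnel$lower) / 2
  norm_exc <- ifelse(exc > 0, ifelse(half > 0, exc / half, exc), 0)
  list(inside = all(exc == 0),
       dist = mean(norm_exc),
       n_outside = sum(exc > 0),
       n_points = nrow(tunnel))
}

#' Uniform perturbation of a candidate vector
#'
#' Draws `n` concrete parameter realizations around a candidate's central
#' values: each searched parameter is drawn uniformly from
#' `[centre - std, centre + std]`, truncated at 0 from below (and at 1 for
#' `a_max`, whose parameter-set invariant is `a_max <= 1`); `p_max` is
#' re-derived from each drawn `k_p`. Draws consume the current R RNG
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param centre named numeric vector of central values over
#'   [searched_parameter_names()].
#' @param pseudo_std named vector of interval half-widths (defaults to
#'   [default_pseudo_std()]); a half-width of 0 returns the centre exactly.
#' @param n number of draws.
#' @param F_sat food-saturation reference used to derive `p_max`.
#' @return an `n x 8` matrix with columns `k_p, a_max, k_a, c_re, spn, c_e,
#'   F_lab, p_max`.
#' @export
perturb_candidate <- function(centre, pseudo_std = default_pseudo_std(),
                              n = 1, F_sat = 1.2e-4) {
  nms <- searched_parameter_names()
  centre <- unlist(centre)[nms]
  if (any(is.na(centre)))
    stop("centre must provide values for: ", paste(nms, collapse = ", "))
  std <- pseudo_std[nms]
  std[is.na(std)] <- 0
  check_nonnegative(std, "pseudo_std")
  draws <- matrix(0, nrow = n, ncol = 8,
                  dimnames = list(NULL, c(nms, "p_max")))
  for (j in seq_along(nms)) {
    x <- if (std[j] > 0) runif(n, centre[j] - std[j], centre[j] + std[j])
         else rep(centre[j], n)
    x <- pmax(0, x)
    if (nms[j] == "a_max") x <- pmin(1, x)
    draws[, j] <- x
  }
  draws[, "p_max"] <- p_max_from_kp(draws[, "k_p"], F_sat)
  draws
}

#' Sequential probability ratio test on a pass/fail stream
#'
#' Wald SPRT of H0: `p >= gamma + epsilon` against H1:
#' `p <= gamma - epsilon` with both error rates equal to `delta`, applied to
#' a stream of Bernoulli outcomes. Used one-sidedly: the test may conclude
#' `reject_below_threshold` (the match probability cannot reach the
#' retention threshold) as soon as the log-likelihood ratio crosses the H1
#' boundary `log((1 - delta) / delta)`, but it never accepts early -
#' estimation simply continues to the end of the stream (`"complete"`).
#'
#' @param stream logical vector of simulation outcomes (TRUE = inside the
#'   tunnels).
#' @param gamma retention threshold.
#' @param epsilon half-width of the SPRT indifference region.
#' @param delta type-I and type-II error rate.
#' @return list with `decision` (`"reject_below_threshold"` or
#'   `"complete"`) and `n_used` (observations consumed).
#' @examples
#' sprt_decide(rep(FALSE, 50))   # rejects after 14 failures at defaults
#' @export
sprt_decide <- function(stream, gamma = 0.70, epsilon = 0.05, delta = 0.01) {
  stopifnot(is.logical(stream), gamma - epsilon > 0, gamma + epsilon < 1)
  p1 <- gamma + epsilon
  p0 <- gamma - epsilon
  la <- log(p0 / p1)
  lb <- log((1 - p0) / (1 - p1))
  bound <- log((1 - delta) / delta)
  llr <- cumsum(ifelse(stream, la, lb))
  hit <- which(llr >= bound)
  if (length(hit) > 0)
    list(decision = "reject_below_threshold", n_used = hit[1])
  else
    list(decision = "complete", n_used = length(stream))
}

#' Monte Carlo match estimation on a generic pass/fail stream
#'
#' The estimation core of the engine, independent of the jellyfish model:
#' given a pre-generated Bernoulli stream (or a generator function), runs
#' the SPRT-pruned Monte Carlo estimate of the pass probability.
#'
#' @param stream logical vector of length `config$n_sims`, or a function
#'   `function(n)` returning one.
#' @param config an [smc_config()].
#' @return list with `theta_hat`, `n_used`, `decided_by`.
#' @examples
#' set.seed(1)
#' smc_estimate(runif(500) < 0.3, smc_config())$theta_hat  # ~0.3
#' @export
smc_estimate <- function(stream, config = smc_config()) {
  if (is.function(stream)) stream <- stream(config$n_sims)
  stopifnot(is.logical(stream), length(stream) >= config$n_sims)
  stream <- stream[seq_len(config$n_sims)]
  if (config$use_sprt) {
    dec <- sprt_decide(stream, config$gamma, config$epsilon, config$delta)
  } else {
    dec <- list(decision = "complete", n_used = config$n_sims)
  }
  used <- stream[seq_len(dec$n_used)]
  list(theta_hat = mean(used), n_used = dec$n_used,
       decided_by = if (dec$decision == "complete") "monte_carlo"
                    else "sprt_reject")
}

# Translate a scenario (plus tunnel) into the flat payload consumed by the
# compiled match loop.
scenario_payload <- function(scenario) {
  fz <- scenario$forcing
  tn <- scenario$tunnels
  if (is.null(tn)) stop("scenario '", scenario$name, "' carries no tunnels")
  list(t = fz$t_day, Ts = fz$T_surface_C,
       Td = as.numeric(fz$T_deep_C), F = fz$F_gC_per_L,
       use_flab = isTRUE(scenario$uses_F_lab),
       initial_cm = cm_from_bd(scenario$initial_bd),
       tun_t = tn$t_day, tun_lo = tn$lower, tun_up = tn$upper,
       var = if (attr(tn, "variable") == "bd") 0L else 1L)
}

#' Estimate a candidate's match probability against scenarios
#'
#' Runs up to `config$n_sims` random simulations of a candidate parameter
#' vector: each simulation draws a concrete realization from the candidate's
#' uniform uncertainty intervals ([perturb_candidate()]), integrates every
#' scenario, and passes when the trajectory stays inside the observation
#' tunnel of every scenario at every tunnel time. The match probability
#' `theta_hat` is the pass fraction; the SPRT prunes the candidate early
#' when the accumulated failures prove the probability cannot reach
#' `gamma`. Per scenario, `score` is the mean number of tunnel times
#' violated per simulation and `dist` the mean normalized excursion.
#'
#' @param centre named numeric vector of candidate central values.
#' @param scenarios list of [scenario()]s (each with tunnels attached).
#' @param config an [smc_config()].
#' @param params fixed-parameter template, a [jelly_params()].
#' @param pseudo_std perturbation half-widths.
#' @param seed integer seed for the candidate's random stream.
#' @param engine `"compiled"` (default) or `"r"` (reference implementation
#'   in plain R; identical draws, used for cross-checking).
#' @return an `evaluation_result` list: `centre`, `theta_hat`, `n_used`,
#'   `k_pass`, `decided_by`, per-scenario `score` and `dist` (named),
#'   `n_points` and the scalar `combined_error`.
#' @export
estimate_match <- function(centre, scenarios, config = smc_config(),
                           params = jelly_params(),
                           pseudo_std = default_pseudo_std(),
                           seed = 1L, engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  set.seed(seed)
  draws <- perturb_candidate(centre, pseudo_std, config$n_sims, params$F_sat)
  payloads <- lapply(scenarios, scenario_payload)
  if (engine == "compiled") {
    res <- match_candidate_cpp(draws, params_for_cpp(params), payloads,
                               config$gamma, config$epsilon, config$delta,
                               config$use_sprt)
  } else {
    res <- match_candidate_r(draws, params, scenarios, config)
  }
  sn <- vapply(scenarios, function(s) s$name, "")
  npts <- vapply(scenarios, function(s) nrow(s$tunnels), 0L)
  weights <- vapply(scenarios, function(s) s$weight, 0)
  score <- setNames(as.numeric(res$score), sn)
  dist <- setNames(as.numeric(res$dist), sn)
  structure(list(centre = centre,
                 theta_hat = res$theta_hat, n_used = res$n_used,
                 k_pass = res$k_pass, decided_by = res$decided_by,
                 score = score, dist = dist,
                 n_points = setNames(npts, sn),
                 combined_error = combined_error(score, dist, npts, weights)),
            class = "evaluation_result")
}

# Plain-R reference of the compiled match loop (same draw stream).
match_candidate_r <- function(draws, params, scenarios, config) {
  n_scen <- length(scenarios)
  out_sum <- dist_sum <- numeric(n_scen)
  k_pass <- 0L
  n_used <- 0L
  decided <- "monte_carlo"
  p1 <- config$gamma + config$epsilon
  p0 <- config$gamma - config$epsilon
  la <- log(p0 / p1); lb <- log((1 - p0) / (1 - p1))
  bound <- log((1 - config$delta) / config$delta)
  for (i in seq_len(config$n_sims)) {
    pset <- set_searched(params, draws[i, searched_parameter_names()])
    pass <- TRUE
    for (s in seq_len(n_scen)) {
      sc <- scenarios[[s]]
      fz <- sc$forcing
      if (isTRUE(sc$uses_F_lab)) fz$F_gC_per_L <- draws[i, "F_lab"]
      tr <- simulate_jelly(sc$initial_bd, fz, pset)
      ck <- check_tunnel(tr, sc$tunnels)
      out_sum[s] <- out_sum[s] + ck$n_outside
      dist_sum[s] <- dist_sum[s] + ck$dist
      if (!ck$inside) pass <- FALSE
    }
    if (pass) k_pass <- k_pass + 1L
    n_used <- i
    if (config$use_sprt && n_used < config$n_sims) {
      llr <- k_pass * la + (n_used - k_pass) * lb
      if (llr >= bound) { decided <- "sprt_reject"; break }
    }
  }
  list(theta_hat = k_pass / n_used, n_used = n_used, k_pass = k_pass,
       decided_by = decided, score = out_sum / n_used,
       dist = dist_sum / n_used)
}

#' Evaluate the whole candidate space and rank accepted vectors
#'
#' Evaluates every candidate of an enumerated grid independently, with a
#' per-candidate seed derived from `master_seed` and the candidate's grid
#' index - so the retained set and all estimates are identical whatever the
#' evaluation order or worker count. Candidates whose estimated match
#' probability exceeds `gamma` are flagged `retained`; all candidates are
#' ranked by combined error (see [combined_error()]).
#'
#' @param candidates data frame from [enumerate_space()] (must carry a
#'   `candidate_index` column).
#' @param scenarios list of [scenario()]s with tunnels.
#' @param config an [smc_config()].
#' @param params fixed-parameter template.
#' @param pseudo_std perturbation half-widths.
#' @param master_seed integer master seed.
#' @param workers number of parallel workers (forked; results identical to
#'   serial).
#' @return data frame, sorted by combined error, with the candidate
#'   columns plus `theta_hat`, `n_used`, `decided_by`, per-scenario
#'   `score_*` and `dist_*`, `combined_error`, `retained` and `rank`.
#' @export
evaluate_space <- function(candidates, scenarios, config = smc_config(),
                           params = jelly_params(),
                           pseudo_std = default_pseudo_std(),
                           master_seed = 1L, workers = 1L) {
  stopifnot("candidate_index" %in% names(candidates))
  sn <- vapply(scenarios, function(s) s$name, "")
  eval_one <- function(i) {
    row <- candidates[i, , drop = FALSE]
    centre <- unlist(row[searched_parameter_names()])
    seed <- candidate_seed(master_seed, row$candidate_index)
    r <- estimate_match(centre, scenarios, config, params, pseudo_std, seed)
    c(theta_hat = r$theta_hat, n_used = r$n_used,
      decided = as.integer(r$decided_by == "sprt_reject"),
      setNames(r$score, paste0("score_", sn)),
      setNames(r$dist, paste0("dist_", sn)),
      combined_error = r$combined_error)
  }
  idx <- seq_len(nrow(candidates))
  rows <- if (workers > 1) {
    parallel::mclapply(idx, eval_one, mc.cores = workers)
  } else {
    lapply(idx, eval_one)
  }
  stats_df <- as.data.frame(do.call(rbind, rows))
  out <- cbind(candidates, stats_df)
  out$decided_by <- ifelse(out$decided == 1, "sprt_reject", "monte_carlo")
  out$decided <- NULL
  out$retained <- out$theta_hat > config$gamma
  out <- out[order(out$combined_error, -out$theta_hat, out$candidate_index), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Deterministic per-candidate seed; keeps within the 32-bit integer range.
candidate_seed <- function(master_seed, candidate_index) {
  as.integer((as.double(master_seed) * 7919 + as.double(candidate_index) *
                104729) %% 2147483647)
}

#' Spearman rank-correlation matrix of accepted candidate vectors
#'
#' Pairwise Spearman correlations between the searched parameters and the
#' SMCE outputs (match probability, per-scenario scores, and median export
#' when present) across accepted candidate vectors, to expose dependencies
#' between parameters that one-at-a-time sensitivity analysis misses. A
#' constant column has no ranks to correlate; its entries are reported as
#' `NA`, not zero.
#'
#' @param results data frame of accepted rows from [evaluate_space()] (or
#'   any numeric table).
#' @param vars columns to correlate; defaults to every searched parameter
#'   plus `theta_hat` and any `score_*`/`dist_*`/`median_export` columns
#'   present.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlogram <- function(results, vars = NULL) {
  if (nrow(results) < 3)
    stop("need at least 3 accepted vectors to correlate")
  if (is.null(vars)) {
    vars <- intersect(c(searched_parameter_names(), "theta_hat",
                        grep("^(score|dist)_", names(results), value = TRUE),
                        "median_export"),
                      names(results))
  }
  m <- as.matrix(results[, vars, drop = FALSE])
  storage.mode(m) <- "double"
  cc <- suppressWarnings(cor(m, method = "spearman"))
  const <- apply(m, 2, function(x) length(unique(x)) == 1)
  cc[const, ] <- NA_real_
  cc[, const] <- NA_real_
  diag(cc) <- 1
  cc
}
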