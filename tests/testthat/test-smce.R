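test_that("perturbation draws uniformly within the pseudo-std interval", {
  centre <- c(k_p = 1.9e-4, a_max = 0.8, k_a = 5e-5, c_re = 2.7,
              spn = 0.7, c_e = 0, F_lab = 9e-6)
  # zero half-widths return the centre exactly
  z <- perturb_candidate(centre, setNames(rep(0, 7), names(centre)), n = 5)
  for (nm in names(centre)) expect_equal(unname(z[, nm]), rep(centre[[nm]], 5))
  expect_equal(unname(z[, "p_max"]), rep(p_max_from_kp(1.9e-4), 5))
  set.seed(3)
  d <- perturb_candidate(centre, default_pseudo_std(), n = 1e5)
  expect_equal(mean(d[, "spn"]), 0.7, tolerance = 1e-3)
  expect_gte(min(d[, "spn"]), 0.65)
  expect_lte(max(d[, "spn"]), 0.75)
  expect_gt(max(d[, "spn"]), 0.749)   # the interval is actually filled
  # nonnegativity truncation confines c_e (centre 0) to [0, std]
  expect_gte(min(d[, "c_e"]), 0)
  expect_lte(max(d[, "c_e"]), 0.025)
  # p_max tracks each drawn k_p
  expect_equal(d[, "p_max"], p_max_from_kp(d[, "k_p"]), ignore_attr = TRUE)
})

test_that("tunnel checking measures excursions in half-width units", {
  p <- jelly_params()
  tr <- simulate_jelly(4.5, forcing_series(0:30, 18, NA, 0), p)
  # midline tunnel: inside, zero distance
  tt <- seq(0, 30, by = 2)
  v <- approx(tr$t_day, tr$bd_cm, tt)$y
  tn <- tunnel_set(tt, v - 0.5, v + 0.5, "bd")
  ck <- check_tunnel(tr, tn)
  expect_true(ck$inside)
  expect_equal(ck$dist, 0)
  expect_equal(ck$n_outside, 0)
  # one point pushed a full half-width beyond the upper bound -> dist 1/n
  lo <- v - 0.5; up <- v + 0.5
  lo[4] <- v[4] - 1.5; up[4] <- v[4] - 0.5   # band now one half-width below
  ck2 <- check_tunnel(tr, tunnel_set(tt, lo, up, "bd"))
  expect_false(ck2$inside)
  expect_equal(ck2$n_outside, 1)
  expect_equal(ck2$dist, 1 / length(tt))
  # degenerate band: inside only on exact equality
  ck3 <- check_tunnel(tr, tunnel_set(tt, v, v, "bd"))
  expect_true(ck3$inside)
  ck4 <- check_tunnel(tr, tunnel_set(tt, v + 1e-9, v + 1e-9, "bd"))
  expect_false(ck4$inside)
})

test_that("an exhausted trajectory is outside from truncation onward", {
  p <- jelly_params()
  tr <- simulate_jelly(0.2, forcing_series(0:2000, 22, NA, 0), p)
  nv <- attr(tr, "n_valid")
  t_end <- tr$t_day[nv]
  tn <- tunnel_set(c(1, t_end + 50, t_end + 100),
                   rep(0.01, 3), rep(30, 3), "bd")
  ck <- check_tunnel(tr, tn)
  expect_false(ck$inside)
  expect_equal(ck$n_outside, 2)
})

test_that("the SPRT rejects hopeless candidates at the Wald boundary", {
  # closed-form all-fail rejection count at the defaults:
  # ceil(log((1-delta)/delta) / log((1-gamma+eps)/(1-gamma-eps))) = 14
  n_reject <- ceiling(log(0.99 / 0.01) / log(0.35 / 0.25))
  expect_equal(n_reject, 14)
  dec <- sprt_decide(rep(FALSE, 100))
  expect_equal(dec$decision, "reject_below_threshold")
  expect_equal(dec$n_used, n_reject)
  # an all-pass stream is never rejected: estimation completes
  dec2 <- sprt_decide(rep(TRUE, 100))
  expect_equal(dec2$decision, "complete")
  expect_equal(dec2$n_used, 100)
  expect_error(sprt_decide(rep(TRUE, 5), gamma = 0.99, epsilon = 0.05))
})

test_that("good candidates are early-rejected with probability <= delta", {
  cfg <- smc_config()
  set.seed(21)
  n_streams <- 2000
  # Wald's guarantee applies above the indifference region: p >= gamma+eps
  rejected <- vapply(seq_len(n_streams), function(i) {
    s <- runif(cfg$n_sims) < (cfg$gamma + cfg$epsilon)
    sprt_decide(s, cfg$gamma, cfg$epsilon, cfg$delta)$decision ==
      "reject_below_threshold"
  }, TRUE)
  tol <- 3 * sqrt(cfg$delta * (1 - cfg$delta) / n_streams)
  expect_lte(mean(rejected), cfg$delta + tol)
})

test_that("Monte Carlo estimation recovers an analytic pass probability", {
  # toy model y = theta, theta ~ U[0,1], property y <= 0.3 -> p = 0.3
  cfg <- smc_config(use_sprt = FALSE)
  set.seed(5)
  est <- smc_estimate(runif(cfg$n_sims) < 0.3, cfg)
  expect_equal(est$n_used, 500)
  expect_equal(est$decided_by, "monte_carlo")
  expect_lt(abs(est$theta_hat - 0.3), 3 * sqrt(0.3 * 0.7 / 500))
  # with pruning on, such a low-p candidate is dispatched quickly
  set.seed(5)
  est2 <- smc_estimate(runif(500) < 0.3, smc_config())
  expect_equal(est2$decided_by, "sprt_reject")
  expect_lt(est2$n_used, 100)
})

make_two_scenarios <- function(width = 2, duration = 20) {
  p <- jelly_params()
  deg <- make_lab_degrowth(duration, initial_bd = 4.5)
  tr <- simulate_jelly(4.5, deg$forcing, p)
  tt <- seq(0, duration, by = 2)
  v <- approx(tr$t_day, tr$bd_cm, tt)$y
  deg$tunnels <- tunnel_set(tt, v - width, v + width, "bd")
  grw <- make_lab_growth(duration, initial_bd = 1, F_lab = 9e-6)
  fzg <- grw$forcing; fzg$F_gC_per_L <- 9e-6
  trg <- simulate_jelly(1, fzg, p)
  vg <- approx(trg$t_day, trg$bd_cm, tt)$y
  grw$tunnels <- tunnel_set(tt, vg - width, vg + width, "bd")
  list(deg = deg, grw = grw, p = p)
}

test_that("match estimation hits the trivial extremes", {
  ss <- make_two_scenarios(width = 1e6)   # effectively unbounded tunnels
  centre <- c(k_p = 1.9e-4, a_max = 0.8, k_a = 5e-5, c_re = 2.7,
              spn = 0.7, c_e = 0, F_lab = 9e-6)
  cfg <- smc_config(n_sims = 50)
  r <- estimate_match(centre, list(ss$deg, ss$grw), cfg, ss$p, seed = 2)
  expect_equal(r$theta_hat, 1)
  expect_equal(r$n_used, 50)
  expect_equal(r$combined_error, 0)
  # an unreachable band: theta 0 and a fast SPRT rejection
  deg0 <- ss$deg
  deg0$tunnels <- tunnel_set(c(5, 10), c(100, 100), c(101, 101), "bd")
  r0 <- estimate_match(centre, list(deg0), cfg, ss$p, seed = 2)
  expect_equal(r0$theta_hat, 0)
  expect_equal(r0$decided_by, "sprt_reject")
  expect_equal(r0$n_used, 14)
})

test_that("compiled and plain-R match engines agree draw for draw", {
  ss <- make_two_scenarios(width = 0.05)   # tight: mixed pass/fail
  centre <- c(k_p = 1.9e-4, a_max = 0.8, k_a = 5e-5, c_re = 2.7,
              spn = 0.7, c_e = 0, F_lab = 9e-6)
  cfg <- smc_config(n_sims = 40, use_sprt = FALSE)
  rc <- estimate_match(centre, list(ss$deg, ss$grw), cfg, ss$p, seed = 9,
                       engine = "compiled")
  rr <- estimate_match(centre, list(ss$deg, ss$grw), cfg, ss$p, seed = 9,
                       engine = "r")
  expect_equal(rc$theta_hat, rr$theta_hat)
  expect_equal(rc$score, rr$score, tolerance = 1e-12)
  expect_equal(rc$dist, rr$dist, tolerance = 1e-12)
  expect_equal(rc$n_used, rr$n_used)
})

test_that("match estimation is deterministic and monotone in tunnel width", {
  centre <- c(k_p = 1.9e-4, a_max = 0.8, k_a = 5e-5, c_re = 2.7,
              spn = 0.7, c_e = 0, F_lab = 9e-6)
  cfg <- smc_config(n_sims = 60, use_sprt = FALSE)
  thetas <- sapply(c(0.02, 0.05, 0.1, 0.3, 1), function(w) {
    ss <- make_two_scenarios(width = w)
    estimate_match(centre, list(ss$deg, ss$grw), cfg, ss$p, seed = 4)$theta_hat
  })
  expect_true(all(diff(thetas) >= 0))   # widening never lowers the match
  ss <- make_two_scenarios(width = 0.05)
  a <- estimate_match(centre, list(ss$deg, ss$grw), cfg, ss$p, seed = 4)
  b <- estimate_match(centre, list(ss$deg, ss$grw), cfg, ss$p, seed = 4)
  expect_identical(a$theta_hat, b$theta_hat)
  expect_identical(a$score, b$score)
})

test_that("space evaluation retains passers and is order-independent", {
  ss <- make_two_scenarios(width = 0.4)
  scns <- list(ss$deg, ss$grw)
  vs <- reduced_search_vectors()
  cands <- enumerate_space(list(spn = vs$spn, c_e = vs$c_e))
  full <- data.frame(k_p = 1.9e-4, a_max = 0.8, k_a = 5e-5, c_re = 2.7,
                     cands[, c("spn", "c_e")], F_lab = 9e-6,
                     candidate_index = cands$candidate_index)
  cfg <- smc_config(n_sims = 40)
  res <- evaluate_space(full, scns, cfg, ss$p, master_seed = 11)
  expect_true(any(res$retained))       # the truth cell passes wide tunnels
  expect_true(all(res$theta_hat[res$retained] > cfg$gamma))
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_true(!is.unsorted(res$combined_error))
  # permuting the candidate order changes nothing per candidate_index
  perm <- full[sample(nrow(full)), ]
  res2 <- evaluate_space(perm, scns, cfg, ss$p, master_seed = 11)
  res2 <- res2[match(res$candidate_index, res2$candidate_index), ]
  expect_equal(res$theta_hat, res2$theta_hat)
  expect_equal(res$combined_error, res2$combined_error)
  expect_equal(res$retained, res2$retained)
})

test_that("the correlogram is a Spearman matrix with honest missing values", {
  set.seed(8)
  df <- data.frame(k_p = runif(5), a_max = runif(5), theta_hat = runif(5))
  df$k_a <- df$k_p^3            # monotone transform: rank correlation 1
  df$c_e <- rep(0.1, 5)         # constant: undefined, reported NA
  cc <- correlogram(df, vars = c("k_p", "a_max", "k_a", "c_e", "theta_hat"))
  expect_equal(diag(cc), setNames(rep(1, 5), colnames(cc)))
  expect_equal(cc["k_p", "k_a"], 1)
  expect_true(all(is.na(cc["c_e", c("k_p", "a_max", "k_a", "theta_hat")])))
  expect_equal(cc, t(cc))
  # brute-force oracle: rank then Pearson
  expect_equal(cc["k_p", "theta_hat"],
               oracle_spearman(df$k_p, df$theta_hat))
  expect_error(correlogram(df[1:2, ]), "at least 3")
})

test_that("the Chernoff-Hoeffding sample size is computed, not assumed", {
  expect_equal(ch_required_n(0.05, 0.01), 1060L)
  # the published run configuration undershoots the bound
  expect_lt(smc_config()$n_sims, ch_required_n(0.05, 0.01))
})
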