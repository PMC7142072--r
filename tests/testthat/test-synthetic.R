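test_that("the synthetic climatology matches the stated seasonal cycle", {
  clim <- synth_climatology()
  expect_equal(nrow(clim), 365)
  # the daily grid need not hit the sinusoid extrema exactly
  expect_equal(min(clim$T_surface_C), 13, tolerance = 1e-4)
  expect_equal(max(clim$T_surface_C), 22, tolerance = 1e-4)
  expect_true(all(clim$T_surface_C >= 13 & clim$T_surface_C <= 22))
  zoo_max <- max(clim$F_gC_per_L)
  expect_gte(zoo_max, 5e-6)
  expect_lte(zoo_max, 6e-6)
  # winter and summer troughs at the floor level
  expect_equal(clim$F_gC_per_L[1], 1e-6, tolerance = 1e-3)
  expect_equal(clim$F_gC_per_L[300], 1e-6, tolerance = 1e-3)
  expect_true(all(clim$T_deep_C == 13))
  # pure function of the spec: identical on re-generation
  expect_identical(clim, synth_climatology())
})

test_that("synthetic tunnels collapse onto the truth at zero noise", {
  spec <- synthetic_spec(noise_frac = 0)
  scn <- make_lab_degrowth()
  tn <- synth_observations(scn, spec)
  expect_equal(tn$lower, tn$upper)
  tr <- simulate_jelly(scn$initial_bd, scn$forcing, spec$truth)
  expect_equal(tn$lower, approx(tr$t_day, tr$bd_cm, tn$t_day)$y,
               tolerance = 1e-12)
  ck <- check_tunnel(tr, tn)
  expect_true(ck$inside)
})

test_that("tunnels widen pointwise with the std multiplier", {
  scn <- make_lab_degrowth()
  set.seed(31)
  t1 <- synth_observations(scn, synthetic_spec(k_std = 1))
  set.seed(31)
  t2 <- synth_observations(scn, synthetic_spec(k_std = 2))
  expect_true(all(t2$lower <= t1$lower))
  expect_true(all(t2$upper >= t1$upper))
  expect_equal((t2$upper - t2$lower), 2 * (t1$upper - t1$lower))
  # reproducible under a fixed seed
  set.seed(31)
  t1b <- synth_observations(scn, synthetic_spec(k_std = 1))
  expect_identical(t1, t1b)
})

test_that("per-point tunnel coverage of the truth matches the t-band analytic rate", {
  # a mean +/- 1 sd band from n replicates contains the true value when
  # |t_{n-1}| < sqrt(n); with n = 5 that probability is ~0.911
  spec <- synthetic_spec()
  scn <- make_lab_degrowth()
  tr <- simulate_jelly(scn$initial_bd, scn$forcing, spec$truth)
  set.seed(77)
  cover <- replicate(100, {
    tn <- synth_observations(scn, spec)
    ck <- check_tunnel(tr, tn)
    1 - ck$n_outside / ck$n_points
  })
  analytic <- 1 - 2 * stats::pt(-sqrt(5), df = 4)
  expect_equal(mean(cover), analytic, tolerance = 0.03)
})

test_that("the SMCE retains the on-grid truth under generous tunnels", {
  # machinery check at the low-noise / wide-tunnel end of the generator:
  # the truth against a grossly wrong competitor, so exactly one of the two
  # candidates can pass
  spec <- synthetic_spec(noise_frac = 0.03, k_std = 8)
  set.seed(12)
  scns <- synth_scenarios(spec)
  truth <- c(k_p = 1.9e-4, a_max = 0.8, k_a = 5e-5, c_re = 2.7,
             spn = 0.7, c_e = 0, F_lab = 9e-6)
  wrong <- c(k_p = 3e-5, a_max = 0.5, k_a = 1.5e-5, c_re = 1,
             spn = 0.4, c_e = 2, F_lab = 0.7e-5)
  cands <- rbind(as.data.frame(as.list(truth)), as.data.frame(as.list(wrong)))
  cands$candidate_index <- 1:2
  res <- evaluate_space(cands, scns, smc_config(n_sims = 60), spec$truth,
                        master_seed = 12)
  expect_equal(sum(res$retained), 1)
  truth_row <- res[res$candidate_index == 1, ]
  expect_true(truth_row$retained)
  expect_gt(truth_row$theta_hat, 0.7)
  expect_equal(truth_row$rank, 1)
  wrong_row <- res[res$candidate_index == 2, ]
  expect_equal(wrong_row$theta_hat, 0)
  expect_equal(wrong_row$decided_by, "sprt_reject")
})

test_that("zero-width tunnels with nonzero pseudo-std retain nothing", {
  spec <- synthetic_spec(noise_frac = 0)
  set.seed(4)
  scns <- synth_scenarios(spec)
  centre <- c(k_p = 1.9e-4, a_max = 0.8, k_a = 5e-5, c_re = 2.7,
              spn = 0.7, c_e = 0, F_lab = 9e-6)
  r <- estimate_match(centre, scns, smc_config(n_sims = 50), spec$truth,
                      seed = 4)
  expect_equal(r$theta_hat, 0)
})

test_that("a synthetic study directory round-trips through its files", {
  dir <- withr::local_tempdir()
  manifest <- synth_study(dir, synthetic_spec(), seed = 5)
  m <- read_run_manifest(file.path(dir, "manifest.yml"))
  expect_equal(m$config$seed, 5)
  expect_setequal(names(m$files), c("lab_degrowth", "lab_growth", "insitu"))
  fz <- read_forcing_csv(file.path(dir, "insitu_forcing.csv"))
  tn <- read_tunnels_csv(file.path(dir, "insitu_tunnel.csv"))
  expect_s3_class(fz, "jelly_forcing")
  expect_equal(attr(tn, "variable"), "bd")
  expect_true(all(tn$lower <= tn$upper))
  # regenerating with the same seed reproduces the tunnels bit for bit
  dir2 <- withr::local_tempdir()
  synth_study(dir2, synthetic_spec(), seed = 5)
  expect_equal(read_tunnels_csv(file.path(dir2, "insitu_tunnel.csv")), tn)
})
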