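test_that("p_max is pinned to k_p through the saturation assumption", {
  expect_equal(p_max_from_kp(0), 0.1399)
  expect_equal(p_max_from_kp(1.2e-4, 1.2e-4), 0.2798)
  expect_equal(p_max_from_kp(1.9e-4, 1.2e-4), 0.1399 * (1 + 19 / 12))
  expect_error(p_max_from_kp(1e-4, 0), "> 0")
  expect_error(p_max_from_kp(-1e-5), ">= 0")
})

test_that("ingestion follows Michaelis-Menten saturation in prey", {
  p <- jelly_params(k_p = 1e-4)
  cm <- cm_from_bd(5)
  expect_equal(ingestion(predation(cm, 18, 0, p), 0), 0)
  sat <- p$p_max * cm^p$b_p * p$t_10p^18
  # half-saturation point: F = k_p
  expect_equal(ingestion(predation(cm, 18, p$k_p, p), p$k_p), sat / 2)
  # saturation limit
  expect_equal(ingestion(predation(cm, 18, 1, p), 1), sat, tolerance = 1e-3)
  # monotone non-decreasing in F
  Fs <- seq(0, 5e-4, length.out = 60)
  I <- vapply(Fs, function(f) ingestion(predation(cm, 18, f, p), f), 0)
  expect_true(all(diff(I) >= 0))
  # linear in F at fixed predation term
  expect_equal(ingestion(0.3, 2e-6), 2 * ingestion(0.3, 1e-6))
})

test_that("assimilated fraction decreases with prey concentration", {
  p <- jelly_params(a_max = 1, k_a = 2e-5)
  expect_equal(assimilation(1e-3, 0, p), 1e-3)
  expect_equal(assimilation(1e-3, p$k_a, p), 1e-3 * (1 - p$a_max / 2))
  expect_lt(assimilation(1e-3, 1, p), 1e-7)   # a_max = 1 starves at saturation
  frac <- vapply(seq(0, 1e-4, length.out = 40),
                 function(f) assimilation(1, f, p), 0)
  expect_true(all(diff(frac) <= 0))
})

test_that("respiration reproduces the 1 g wet-mass reference and the Q10 law", {
  p <- jelly_params()
  cm1 <- cm_from_bd((1 / 0.075)^(1 / 2.993))   # carbon mass of a 1 g WM animal
  r0 <- respiration(cm1, 0, p)
  expect_equal(r0$R_O2, 2.80, tolerance = 1e-9)
  expect_equal(r0$R_C, 2.80 * 0.447 * 2.28e-5, tolerance = 1e-9)
  # Q10: +10 degC multiplies any temperature-dependent rate by t_10^10
  for (T in c(0, 7, 13)) {
    expect_equal(respiration(cm1, T + 10, p)$R_O2 / respiration(cm1, T, p)$R_O2,
                 p$t_10r^10)
    cm <- cm_from_bd(6)
    expect_equal(predation(cm, T + 10, 2e-6, p) / predation(cm, T, 2e-6, p),
                 p$t_10p^10)
  }
  # carbon-mass basis switch changes the allometric base mass
  pcm <- jelly_params(respiration_mass_basis = "cm")
  expect_equal(respiration(1, 0, pcm)$R_O2, 2.80, tolerance = 1e-9)
})

test_that("excretion scales respired carbon", {
  expect_equal(excretion(2e-4, 0), 0)
  expect_equal(excretion(2e-4, 1), 2e-4)
  expect_equal(excretion(2e-4, 0.5), 1e-4)
})

test_that("reproduction is gated at the maturity bell diameter", {
  p <- jelly_params()
  expect_equal(reproduction(cm_from_bd(3.9), p), 0)
  cm4 <- cm_from_bd(4)
  expect_equal(reproduction(cm4, p),
               p$a_re * 4^p$b_re * p$W_e * p$c_re * p$spn,
               tolerance = 1e-9)
  expect_equal(reproduction(cm4, jelly_params(c_re = 0)), 0)
  expect_equal(reproduction(cm4, jelly_params(spn = 0)), 0)
  # the egg number is hundreds to thousands for adults
  eggs <- p$a_re * c(4.5, 10)^p$b_re
  expect_true(all(eggs > 50 & eggs < 1e4))
})

test_that("flux breakdown satisfies the carbon bookkeeping exactly", {
  set.seed(11)
  p <- jelly_params(c_e = 0.4)
  for (i in 1:25) {
    cm <- runif(1, 1e-4, 0.5)
    temps <- if (i %% 2 == 0) c(runif(1, 13, 22), 13) else runif(1, 13, 22)
    F <- runif(1, 0, 1e-5)
    fx <- flux_breakdown(cm, temps, F, p)
    expect_identical(fx$Eg, fx$I - fx$A)
    expect_identical(fx$dG, fx$A - (fx$R_C + fx$Ex + fx$Re))
    expect_true(fx$I >= 0 && fx$A >= 0 && fx$Eg >= -1e-20)
    expect_equal(unlist(fx), oracle_fluxes(cm, temps, F, p), tolerance = 1e-12)
  }
})

test_that("parameter-set invariants are enforced", {
  expect_error(jelly_params(a_max = 1.2), "a_max")
  expect_error(jelly_params(t_10 = 0.9), "t_10")
  expect_error(jelly_params(spn = -0.1), ">= 0")
  p <- jelly_params()
  expect_equal(p$p_max, p_max_from_kp(p$k_p, p$F_sat))
  p2 <- set_searched(p, c(k_p = 5e-5, c_e = 0.2))
  expect_equal(p2$p_max, p_max_from_kp(5e-5, p$F_sat))
  expect_equal(p2$c_e, 0.2)
})
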