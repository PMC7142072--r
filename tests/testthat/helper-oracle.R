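# Independent brute-force re-implementations used as oracles. These
# deliberately do not call the package's kernel: they transliterate the
# budget equations directly so the fast path can be checked against them.

oracle_fluxes <- function(cm, temps, F, p) {
  bd <- (cm * 1000 / 0.26)^(1 / 3.017)
  wm <- 0.075 * bd^2.993
  P <- I <- A <- RO2 <- 0
  for (T in temps) {
    Pk <- p$p_max * cm^p$b_p * p$t_10p^T / (F + p$k_p)
    Ik <- Pk * F
    Ak <- Ik * (1 - p$a_max * F / (F + p$k_a))
    mass <- if (p$respiration_mass_basis == "wm") wm else cm
    Rk <- p$R_o * mass^p$b_r * p$t_10r^T
    P <- P + Pk; I <- I + Ik; A <- A + Ak; RO2 <- RO2 + Rk
  }
  nt <- length(temps)
  P <- P / nt; I <- I / nt; A <- A / nt; RO2 <- RO2 / nt
  RC <- RO2 * p$beta * p$alpha
  Ex <- RC * p$c_e
  Re <- 0
  if (bd >= p$maturity_bd) {
    size <- switch(p$reproduction_size_basis,
                   bd_cm = bd, cm_mg = cm * 1000, cm_g = cm)
    Re <- p$a_re * size^p$b_re * p$W_e * p$c_re * p$spn
  }
  c(P = P, I = I, A = A, R_O2 = RO2, R_C = RC, Ex = Ex, Re = Re,
    Eg = I - A, dG = A - (RC + Ex + Re))
}

oracle_simulate <- function(initial_bd, forcing, p) {
  cm <- 0.26 * initial_bd^3.017 / 1000
  n <- nrow(forcing)
  cms <- numeric(n)
  for (i in seq_len(n)) {
    cms[i] <- cm
    temps <- forcing$T_surface_C[i]
    if (!is.na(forcing$T_deep_C[i])) temps <- c(temps, forcing$T_deep_C[i])
    fx <- oracle_fluxes(cm, temps, forcing$F_gC_per_L[i], p)
    if (i < n) {
      cm <- cm + fx[["dG"]] * (forcing$t_day[i + 1] - forcing$t_day[i])
      if (cm <= 0) return(list(cm = cms[seq_len(i)], exhausted = TRUE))
    }
  }
  list(cm = cms, exhausted = FALSE)
}

# Spearman through explicit ranking + Pearson on the ranks.
oracle_spearman <- function(x, y) {
  cor(rank(x), rank(y), method = "pearson")
}

# A small viable forcing mixing constant and varying conditions.
mixed_forcing <- function(days = 30) {
  forcing_series(0:days,
                 T_surface = 16 + 4 * sin(2 * pi * (0:days) / 20),
                 T_deep = 13,
                 F = 5e-6 + 4e-6 * cos(2 * pi * (0:days) / 15)^2)
}
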