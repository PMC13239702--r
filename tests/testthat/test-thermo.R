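test_that("Gibbs, enthalpy and entropy profiles follow their closed forms", {
  tC <- seq(0, 90, 5)
  x <- 1 / (tC + 273.15)

  # constant lnK = 0: dG identically zero (the endergonic/exergonic border)
  ser0 <- data.frame(inv_T_K = x, lnK = rep(0, length(x)), sigma_lnK = 0)
  f0 <- fit_model(ser0, "poly2")
  expect_equal(gibbs_profile(f0, tC), rep(0, length(tC)), tolerance = 1e-9)

  # lnK = 9.316 at 310.15 K -> dG ~ -24.02 kJ/mol
  serc <- data.frame(inv_T_K = x, lnK = rep(9.316, length(x)), sigma_lnK = 0)
  fc <- fit_model(serc, "poly2")
  dG37 <- gibbs_profile(fc, 37)
  expect_equal(dG37, -8.314 * 310.15 * 9.316 / 1000, tolerance = 1e-9)
  expect_equal(round(dG37, 2), -24.02)

  # positive lnK everywhere -> exergonic everywhere
  expect_true(all(gibbs_profile(fc) < 0))

  # linear fit: dH constant at -R b
  serl <- data.frame(inv_T_K = x, lnK = 4 - 3000 * x, sigma_lnK = 0)
  fl <- fit_linear_vh(serl)$fit
  expect_equal(enthalpy_profile(fl, tC), rep(8.314 * 3000 / 1000, length(tC)),
               tolerance = 1e-6)

  # poly2: dH(T) = -R (b + 2c/T)
  co <- c(a = 1, b = -2000, c = 1e5)
  serq <- data.frame(inv_T_K = x,
                     lnK = co[1] + co[2] * x + co[3] * x^2, sigma_lnK = 0)
  fq <- fit_model(serq, "poly2")
  T0 <- 300
  expect_equal(enthalpy_profile(fq, T0 - 273.15),
               -8.314 * (co[[2]] + 2 * co[[3]] / T0) / 1000, tolerance = 1e-6)

  # dS = (dH - dG)/T and the Gibbs-Helmholtz identity
  dS <- entropy_profile(-24.02, -30, 37)
  expect_equal(dS, 1000 * (-30 + 24.02) / 310.15, tolerance = 1e-9)
  expect_equal(round(dS, 1), -19.3)

  prof <- thermo_profile(fq, tC)
  expect_equal(prof$dG_kJ_mol,
               prof$dH_kJ_mol - (tC + 273.15) * prof$dS_J_molK / 1000,
               tolerance = 1e-9)

  expect_error(gibbs_profile(fq, c(-20, 50)), "outside")
})

test_that("heat-capacity profiles match analytic second derivatives", {
  tC <- seq(0, 90, 5)
  x <- 1 / (tC + 273.15)
  serl <- data.frame(inv_T_K = x, lnK = 4 - 3000 * x, sigma_lnK = 0)
  fl <- fit_linear_vh(serl)$fit
  expect_equal(heat_capacity_profile(fl, tC), rep(0, length(tC)))

  co <- c(1, -2000, 1e5)
  serq <- data.frame(inv_T_K = x,
                     lnK = co[1] + co[2] * x + co[3] * x^2, sigma_lnK = 0)
  fq <- fit_model(serq, "poly2")
  expect_equal(1000 * heat_capacity_profile(fq, 300 - 273.15),
               2 * 8.314 * co[3] / 300^2, tolerance = 1e-6)
  expect_equal(round(1000 * heat_capacity_profile(fq, 300 - 273.15), 1), 18.5)

  # constant-dCp truth: recovered dCp constant at the generating value
  law <- vh_law(-30e3, -50, dCp = -1.5e3, T_ref = 310.15)
  ser <- make_k_series(law, seq(0, 90, 5))
  f <- fit_const_cp_vh(ser, T_ref = 310.15)$fit
  dCp <- heat_capacity_profile(f, tC)
  expect_lt(max(abs(dCp + 1.5)) / 1.5, 0.01)
  # and dH(T) is linear in T with slope dCp
  dH <- enthalpy_profile(f, tC)
  slope <- coef(lm(dH ~ tC))[2]
  expect_lt(abs(slope + 1.5) / 1.5, 0.01)
})

test_that("analytic model derivatives agree with central differences", {
  tC <- seq(0, 90, 5)
  x <- 1 / (tC + 273.15)
  set.seed(2)
  y <- 5 - 2500 * x + 3e5 * x^2 + rnorm(length(x), sd = 0.05)
  ser <- data.frame(inv_T_K = x, lnK = y, sigma_lnK = 0.05)
  h <- 1e-6 * mean(x)
  xg <- seq(min(x) + 2 * h, max(x) - 2 * h, length.out = 41)
  for (fam in c("poly2", "poly4", "boltzmann", "exponential")) {
    f <- fit_model(ser, fam)
    if (!f$converged) next
    num1 <- (eval_vh_fit(f, xg + h) - eval_vh_fit(f, xg - h)) / (2 * h)
    ana1 <- eval_vh_fit(f, xg, deriv = 1L)
    expect_lt(max(abs(num1 - ana1) / pmax(abs(ana1), 1e-8)), 1e-5)
    num2 <- (eval_vh_fit(f, xg + h, deriv = 1L) -
             eval_vh_fit(f, xg - h, deriv = 1L)) / (2 * h)
    ana2 <- eval_vh_fit(f, xg, deriv = 2L)
    expect_lt(max(abs(num2 - ana2) / pmax(abs(ana2), 1e-6)), 1e-4)
  }
})

test_that("full pipeline on linear van't Hoff truth returns the generating constants", {
  cfg <- experiment_config(Pt = 50e-6, temperatures = seq(0, 90, 5))
  law_FI <- vh_law(-30e3, -50)
  law_FS <- vh_law(-20e3, -20)
  w <- generate_scenario(law_FI, law_FS, cfg, sigma_phi = 0)
  ks <- k_coupled(w, cfg, "F-I")
  fit <- fit_linear_vh(ks)$fit
  tC <- seq(0, 90, 5)
  expect_lt(max(abs(enthalpy_profile(fit, tC) - (-30))) / 30, 1e-6)
  prof <- thermo_profile(fit, tC)
  expect_lt(max(abs(prof$dS_J_molK - (-50))) / 50, 1e-6)
  expect_lt(max(abs(prof$dCp_kJ_molK)), 1e-9)
})

test_that("feature extraction locates crossings and extrema with border flags", {
  tC <- seq(0, 90, 0.5)
  # symmetric parabola in T centred at 40 degC (via dG = a (T - T0)^2 + c)
  TK <- tC + 273.15
  lnK <- -(0.01 * (tC - 40)^2 - 10) * 1000 / (8.314 * TK)
  ser <- data.frame(inv_T_K = 1 / TK, lnK = lnK, sigma_lnK = 0)
  f <- fit_model(ser, "poly4")
  prof <- thermo_profile(f, tC)
  feats <- extract_features(prof)
  mins <- subset(feats$extrema, quantity == "dG_kJ_mol" & type == "min")
  expect_equal(nrow(mins), 1L)
  expect_lt(abs(mins$temperature_C - 40), 1)

  # monotone linear dH crossing zero: construct lnK with known dH root
  # dH(T) = 2 (T - 310.15) kJ/mol -> lnK'(x) = -1000*2*(1/x - 310.15)/R
  law <- vh_law(0, 30, dCp = 2e3, T_ref = 310.15)
  ser2 <- make_k_series(law, seq(0, 90, 5))
  f2 <- fit_const_cp_vh(ser2, T_ref = 310.15)$fit
  prof2 <- thermo_profile(f2, tC)
  feats2 <- extract_features(prof2)
  zc <- subset(feats2$zero_crossings, quantity == "dH_kJ_mol")
  expect_equal(nrow(zc), 1L)
  expect_lt(abs(zc$temperature_C - (310.15 - 273.15)), 0.5)

  # constant-sign quantity: no crossings of dCp (constant +2 kJ/mol/K)
  expect_false("dCp_kJ_molK" %in% feats2$zero_crossings$quantity)

  # features near the domain border carry the low-confidence flag
  law3 <- vh_law(0, 30, dCp = 2e3, T_ref = 274.15)  # dH root at 1 degC
  ser3 <- make_k_series(law3, seq(0, 90, 5))
  f3 <- fit_const_cp_vh(ser3, T_ref = 274.15)$fit
  feats3 <- extract_features(thermo_profile(f3, tC))
  zc3 <- subset(feats3$zero_crossings, quantity == "dH_kJ_mol")
  expect_true(all(zc3$low_confidence))

  # compensation statistic is defined and near-perfect for this smooth case
  expect_true(abs(feats2$compensation$correlation) <= 1)
})

test_that("band profiles propagate lnK shifts and enforce the envelope", {
  tC <- seq(0, 90, 5)
  x <- 1 / (tC + 273.15)
  y <- 3 - 2000 * x + 2e5 * x^2

  # coincident bands -> zero-width profile bands
  ser0 <- data.frame(inv_T_K = x, lnK = y, sigma_lnK = 0)
  f0 <- fit_error_bands(ser0, fit_model(ser0, "poly2"))
  p0 <- thermo_profile(f0, tC)
  expect_lt(max(abs(p0$dG_kJ_mol_hi - p0$dG_kJ_mol_lo)), 1e-9)

  # +/- sigma lnK shift maps to a -/+ R T sigma shift in dG
  sig <- 0.3
  ser1 <- data.frame(inv_T_K = x, lnK = y, sigma_lnK = sig)
  f1 <- fit_error_bands(ser1, fit_model(ser1, "poly2"))
  p1 <- thermo_profile(f1, tC)
  TK <- tC + 273.15
  expect_equal(p1$dG_kJ_mol_lo, p1$dG_kJ_mol - 8.314 * TK * sig / 1000,
               tolerance = 1e-8)
  expect_equal(p1$dG_kJ_mol_hi, p1$dG_kJ_mol + 8.314 * TK * sig / 1000,
               tolerance = 1e-8)

  # envelope ordering holds per point for every quantity
  for (q in c("dG_kJ_mol", "dH_kJ_mol", "dS_J_molK", "dCp_kJ_molK")) {
    expect_true(all(p1[[paste0(q, "_hi")]] >= p1[[paste0(q, "_lo")]]))
  }

  # a fit without band fits yields a profile without band columns
  p2 <- thermo_profile(fit_model(ser0, "poly2"), tC)
  expect_false(any(grepl("_hi$", names(p2))))
})
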