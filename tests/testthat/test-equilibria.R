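# Expanded algebraic forms of the transition constants, used as
# independent oracles against the compact mass-action implementations.
k_FT_expanded <- function(F, Tb, Pt, Lt) 1 / (Pt * (Lt / Tb - 1) - F)
k_FI_expanded <- function(F, I, S, Pt, Lt) {
  1 / (Pt * (Lt / I - 1 - S / I) - F + S - Lt * S / I + S^2 / I)
}
k_FS_expanded <- function(F, I, S, Pt, Lt) k_FI_expanded(F, S, I, Pt, Lt)

test_that("weights map to concentrations with mass conservation", {
  cfg <- experiment_config(Pt = 100e-6, temperatures = c(10, 20, 30))
  w <- weight_series(c(10, 20, 30), c(100, 50, 20), c(0, 25, 30),
                     c(0, 25, 50))
  conc <- weights_to_concentrations(w, cfg)
  expect_equal(conc$F[1], 20e-6)
  expect_equal(unlist(conc[2, c("F", "I", "S")], use.names = FALSE),
               c(10e-6, 5e-6, 5e-6))
  expect_equal(conc$F + conc$I + conc$S, rep(cfg$Lt, 3), tolerance = 1e-12)
  expect_equal(conc$T_bound, conc$I + conc$S)
  expect_error(weight_series(10, -5, 55, 50), "non-negative")
  expect_error(weight_series(10, 50, 30, 30), "sum to 100")
})

test_that("total-binding constant matches mass action and its printed expansion", {
  cfg <- experiment_config(Pt = 100e-6, temperatures = 25)
  ks <- k_total(weight_series(25, 50, 25, 25), cfg)
  expect_equal(ks$K, 10e-6 / (10e-6 * 90e-6), tolerance = 1e-12)
  expect_equal(ks$lnK, log(1e4 / 0.9), tolerance = 1e-9)
  expect_equal(round(ks$lnK, 3), 9.316)

  # expanded printed form agrees on random valid states
  st <- random_states(1000, seed = 1)
  for (i in seq_len(nrow(st))) {
    cfg_i <- experiment_config(Pt = st$Pt[i], Lt = st$Lt[i], temperatures = 25)
    w_i <- weight_series(25, st$phi_F[i], st$phi_I[i], st$phi_S[i])
    conc <- weights_to_concentrations(w_i, cfg_i)
    k1 <- k_total(w_i, cfg_i)$K
    k2 <- k_FT_expanded(conc$F, conc$T_bound, st$Pt[i], st$Lt[i])
    expect_lt(abs(k1 - k2) / k2, 1e-9)
  }

  # degenerate points are excluded with reasons, not errors
  w0 <- weight_series(c(10, 20), c(100, 0), c(0, 60), c(0, 40))
  ks0 <- k_total(w0, cfg)
  ex <- attr(ks0, "excluded_points")
  expect_equal(nrow(ks0), 0)
  expect_setequal(ex$reason, c("numerator zero", "free ligand zero"))
})

test_that("coupled transition constants obey the shared-denominator identities", {
  cfg <- experiment_config(Pt = 50e-6, temperatures = 25)
  w <- weight_series(25, 25, 50, 25)
  kFI <- k_coupled(w, cfg, "F-I")
  kFS <- k_coupled(w, cfg, "F-S")
  expect_equal(kFI$K, 10e-6 / (5e-6 * 35e-6), tolerance = 1e-12)
  expect_equal(kFS$K, 5e-6 / (5e-6 * 35e-6), tolerance = 1e-12)

  st <- random_states(1000, seed = 2)
  for (i in seq_len(nrow(st))) {
    cfg_i <- experiment_config(Pt = st$Pt[i], Lt = st$Lt[i], temperatures = 25)
    w_i <- weight_series(25, st$phi_F[i], st$phi_I[i], st$phi_S[i])
    conc <- weights_to_concentrations(w_i, cfg_i)
    kfi <- k_coupled(w_i, cfg_i, "F-I")$K
    kfs <- k_coupled(w_i, cfg_i, "F-S")$K
    kis <- k_interconversion(w_i, cfg_i)$K
    expect_lt(abs(kfi - k_FI_expanded(conc$F, conc$I, conc$S,
                                      st$Pt[i], st$Lt[i])) / kfi, 1e-9)
    expect_lt(abs(kfs - k_FS_expanded(conc$F, conc$I, conc$S,
                                      st$Pt[i], st$Lt[i])) / kfs, 1e-9)
    # K_I-S == K_F-S / K_F-I wherever all three are defined
    expect_lt(abs(kis - kfs / kfi) / kis, 1e-9)
  }

  # with the strong state unpopulated, F-I reduces to the total-binding form
  w_noS <- weight_series(25, 40, 60, 0)
  kfi <- k_coupled(w_noS, cfg, "F-I")$K
  kft <- k_total(w_noS, cfg)$K
  expect_equal(kfi, kft, tolerance = 1e-12)
})

test_that("interconversion constant is the weight ratio with exclusions", {
  cfg <- experiment_config(Pt = 100e-6, temperatures = c(10, 20, 35))
  w <- weight_series(c(10, 20, 35), c(20, 50, 60), c(40, 25, 40),
                     c(40, 25, 0))
  ks <- k_interconversion(w, cfg)
  expect_equal(ks$K, c(1, 1), tolerance = 1e-12)
  expect_equal(ks$lnK, c(0, 0))
  ex <- attr(ks, "excluded_points")
  expect_equal(ex$temperature_C, 35)
  expect_match(ex$reason, "strong component zero")
  w2 <- weight_series(10, 25, 50, 25)
  expect_equal(k_interconversion(w2)$K, 0.5)
})

test_that("error propagation is first-order Gaussian with the analytic I-S limit", {
  cfg <- experiment_config(Pt = 100e-6, temperatures = 25)
  w0 <- weight_series(25, 40, 35, 25, sigma_phi = 0)
  expect_equal(propagate_weight_errors(w0, cfg, "F-T"), 0)

  w <- weight_series(25, 40, 35, 25, sigma_phi = 1.2)
  s_is <- propagate_weight_errors(w, cfg, "I-S")
  expect_equal(s_is, 1.2 * sqrt(1 / 35^2 + 1 / 25^2), tolerance = 1e-6)

  # doubling sigma doubles sigma_lnK for every transition
  w2 <- weight_series(25, 40, 35, 25, sigma_phi = 2.4)
  for (tr in c("F-I", "F-S", "F-T", "I-S")) {
    expect_equal(propagate_weight_errors(w2, cfg, tr),
                 2 * propagate_weight_errors(w, cfg, tr),
                 tolerance = 1e-9)
  }
})

test_that("forward solver inverts the coupled model exactly", {
  cfg <- experiment_config(Pt = 100e-6, temperatures = 25)
  none <- solve_forward(0, 0, cfg)
  expect_equal(none$F, cfg$Lt)
  expect_equal(none$I + none$S, 0)

  # bisection oracle on the free-ligand equation
  bisect_F <- function(K_FI, K_FS, Pt, Lt) {
    g <- function(f) {
      Pfree <- Pt - (Lt - f)
      (K_FI + K_FS) * f * Pfree - (Lt - f)
    }
    uniroot(g, c(1e-15, Lt), tol = 1e-18)$root
  }
  sol <- solve_forward(5e4, 5e4, cfg)
  expect_equal(sol$F, bisect_F(5e4, 5e4, cfg$Pt, cfg$Lt), tolerance = 1e-9)
  expect_equal(sol$F * 1e6, 2.170, tolerance = 1e-3)
  expect_equal(sol$I * 1e6, 8.915, tolerance = 1e-3)

  # round trip through k_coupled over random K pairs, plus conservation
  set.seed(9)
  for (i in 1:50) {
    K <- 10^runif(2, 2, 7)
    s <- solve_forward(K[1], K[2], cfg)
    expect_lt(abs(s$F + s$I + s$S - cfg$Lt), 1e-12)
    expect_lt(abs(s$I + s$S + s$P_free - cfg$Pt), 1e-12)
    w <- weight_series(25, 100 * s$F / cfg$Lt, 100 * s$I / cfg$Lt,
                       100 * s$S / cfg$Lt)
    expect_lt(abs(k_coupled(w, cfg, "F-I")$K - K[1]) / K[1], 1e-9)
    expect_lt(abs(k_coupled(w, cfg, "F-S")$K - K[2]) / K[2], 1e-9)
  }
})

test_that("scenario generation round-trips and respects its van't Hoff laws", {
  cfg <- experiment_config(Pt = 50e-6, temperatures = seq(0, 90, 5))
  law_FI <- vh_law(-25e3, -35, -1.2e3)
  law_FS <- vh_law(-35e3, -60, 0)
  w <- generate_scenario(law_FI, law_FS, cfg, sigma_phi = 0)
  truth <- attr(w, "truth_lnK")
  expect_lt(max(abs(k_coupled(w, cfg, "F-I")$lnK - truth$lnK_FI)), 1e-9)
  expect_lt(max(abs(k_coupled(w, cfg, "F-S")$lnK - truth$lnK_FS)), 1e-9)
  expect_lt(max(abs(k_interconversion(w, cfg)$lnK - truth$lnK_IS)), 1e-9)

  # determinism for a fixed seed
  n1 <- generate_scenario(law_FI, law_FS, cfg, sigma_phi = 1.5, seed = 21)
  n2 <- generate_scenario(law_FI, law_FS, cfg, sigma_phi = 1.5, seed = 21)
  expect_identical(as.data.frame(n1), as.data.frame(n2))
  expect_true(all(abs(n1$phi_F + n1$phi_I + n1$phi_S - 100) < 1e-9))
  expect_true(all(n1$phi_F >= 0 & n1$phi_I >= 0 & n1$phi_S >= 0))

  # zero-dCp laws give exactly linear van't Hoff data
  w_lin <- generate_scenario(vh_law(-30e3, -50), vh_law(-20e3, -20), cfg, 0)
  lnK <- k_coupled(w_lin, cfg, "F-I")$lnK
  x <- k_coupled(w_lin, cfg, "F-I")$inv_T_K
  resid <- resid(lm(lnK ~ x))
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("weight and K tables round-trip through CSV", {
  cfg <- experiment_config(Pt = 50e-6, temperatures = seq(10, 50, 10))
  w <- generate_scenario(vh_law(-25e3, -35), vh_law(-35e3, -60), cfg,
                         sigma_phi = 1, seed = 4)
  wp <- withr::local_tempfile(fileext = ".csv")
  write_weight_series(w, wp)
  r <- read_weight_series(wp)
  expect_equal(as.data.frame(r), as.data.frame(w), tolerance = 1e-12,
               ignore_attr = TRUE)

  ks <- k_total(w, cfg)
  kp <- withr::local_tempfile(fileext = ".csv")
  write_k_series(ks, kp)
  d <- read.csv(kp)
  expect_equal(d$lnK, ks$lnK, tolerance = 1e-12)
  expect_equal(d$KD_mol_per_L, 1 / ks$K, tolerance = 1e-12)
})
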