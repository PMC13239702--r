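# Coupled 1:1 binding equilibria: spectral weights -> concentrations ->
# transition binding constants, with per-point exclusions, Gaussian error
# propagation, and the exact forward solver used by the synthetic-data
# generator.

#' Gas constant, J/(mol K)
#' @export
R_GAS <- 8.314

# Numerical floor for concentrations in denominators (mol/L).
EPS_CONC <- 1e-10

#' Experiment configuration
#'
#' Total protein and ligand concentrations, the standard concentration for
#' making bimolecular equilibrium constants dimensionless, a concentration
#' regime label, and the temperature grid of the series.
#'
#' @param Pt Total protein concentration, mol/L (> 0). Typical regimes:
#'   50e-6 (L), 100e-6 (M), 200e-6 (H).
#' @param Lt Total spin-labeled ligand concentration, mol/L (default
#'   20e-6).
#' @param regime Label, one of "L", "M", "H".
#' @param temperatures Strictly increasing temperature grid, degC.
#' @param c_std Standard concentration, mol/L (default 1).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(Pt, Lt = 20e-6, regime = c("L", "M", "H"),
                              temperatures = seq(0, 90, by = 5),
                              c_std = 1) {
  regime <- match.arg(regime)
  if (!is.finite(Pt) || Pt <= 0) stop("Pt must be > 0")
  if (!is.finite(Lt) || Lt <= 0) stop("Lt must be > 0")
  temperatures <- as.numeric(temperatures)
  if (any(diff(temperatures) <= 0)) {
    stop("temperatures must be strictly increasing")
  }
  structure(list(Pt = Pt, Lt = Lt, regime = regime,
                 temperatures = temperatures, c_std = c_std),
            class = "experiment_config")
}

#' Per-temperature spectral weight series
#'
#' @param temperature Temperature grid, degC.
#' @param phi_F,phi_I,phi_S Component weights in percent; each triple must
#'   be non-negative and sum to 100 within 0.5 (triples are renormalized to
#'   exactly 100).
#' @param sigma_phi Absolute weight error in percentage points (one value
#'   per temperature, applied to each of the three weights; the spectral
#'   RMSD convention).
#' @return A data.frame of class `weight_series` with columns
#'   `temperature_C`, `phi_F`, `phi_I`, `phi_S`, `sigma_phi`.
#' @export
weight_series <- function(temperature, phi_F, phi_I, phi_S,
                          sigma_phi = 0) {
  n <- length(temperature)
  sigma_phi <- rep_len(sigma_phi, n)
  stopifnot(length(phi_F) == n, length(phi_I) == n, length(phi_S) == n)
  if (any(c(phi_F, phi_I, phi_S) < 0)) stop("weights must be non-negative")
  if (any(sigma_phi < 0)) stop("sigma_phi must be non-negative")
  tot <- phi_F + phi_I + phi_S
  if (any(abs(tot - 100) > 0.5)) {
    stop("weight triples must sum to 100 within 0.5")
  }
  out <- data.frame(temperature_C = as.numeric(temperature),
                    phi_F = 100 * phi_F / tot,
                    phi_I = 100 * phi_I / tot,
                    phi_S = 100 * phi_S / tot,
                    sigma_phi = sigma_phi)
  class(out) <- c("weight_series", "data.frame")
  out
}

#' Convert spectral weights to species concentrations
#'
#' The composite spectrum is normalized to a constant total ligand
#' concentration, so each species concentration is
#' `[X] = phi_X / 100 * Lt`.
#'
#' @param w A [weight_series()].
#' @param cfg An [experiment_config()].
#' @return A data.frame of class `concentration_series` with columns
#'   `temperature_C`, `F`, `I`, `S`, `T_bound` (= I + S), mol/L.
#' @export
weights_to_concentrations <- function(w, cfg) {
  stopifnot(inherits(w, "weight_series"), inherits(cfg, "experiment_config"))
  out <- data.frame(temperature_C = w$temperature_C,
                    F = w$phi_F / 100 * cfg$Lt,
                    I = w$phi_I / 100 * cfg$Lt,
                    S = w$phi_S / 100 * cfg$Lt)
  out$T_bound <- out$I + out$S
  class(out) <- c("concentration_series", "data.frame")
  out
}

# Kelvin from Celsius.
as_kelvin <- function(temp_C) temp_C + 273.15

# Assemble a k_series data.frame from retained points.
new_k_series <- function(transition, temperature_C, lnK, K, sigma_lnK,
                         excluded) {
  out <- data.frame(temperature_C = temperature_C,
                    inv_T_K = 1 / as_kelvin(temperature_C),
                    lnK = lnK, sigma_lnK = sigma_lnK, K = K)
  class(out) <- c("k_series", "data.frame")
  attr(out, "transition") <- transition
  attr(out, "excluded_points") <- excluded
  out
}

#' @export
print.k_series <- function(x, ...) {
  cat(sprintf("<k_series> transition %s, %d retained points\n",
              attr(x, "transition"), nrow(x)))
  print.data.frame(x, ...)
  ex <- attr(x, "excluded_points")
  if (!is.null(ex) && nrow(ex) > 0) {
    cat("excluded:\n")
    print.data.frame(ex)
  }
  invisible(x)
}

# lnK (dimensionless) for one weight triple. Bimolecular transitions are
# multiplied by c_std before the log so ln K refers to the standard state;
# the I-S interconversion is a plain weight ratio. Returns list(lnK, K,
# reason): reason is NA when the point is retained, otherwise why not.
lnK_point <- function(phi, cfg, transition) {
  Lt <- cfg$Lt; Pt <- cfg$Pt
  F <- phi[1] / 100 * Lt
  I <- phi[2] / 100 * Lt
  S <- phi[3] / 100 * Lt
  Tb <- I + S
  fail <- function(reason) list(lnK = NA_real_, K = NA_real_, reason = reason)
  if (transition == "I-S") {
    if (phi[3] <= 0) return(fail("strong component zero"))
    if (phi[2] <= 0) return(fail("intermediate component zero"))
    K <- phi[3] / phi[2]
    return(list(lnK = log(K), K = K, reason = NA_character_))
  }
  if (F <= EPS_CONC) return(fail("free ligand zero"))
  if (transition == "F-T") {
    if (Tb <= EPS_CONC) return(fail("numerator zero"))
    den <- Pt - Tb
    if (den <= EPS_CONC) return(fail("free protein zero"))
    K <- Tb / (F * den)
  } else {
    Pfree <- Pt - I - S
    if (Pfree <= EPS_CONC) return(fail("free protein zero"))
    num <- if (transition == "F-I") I else S
    if (num <= EPS_CONC) return(fail("numerator zero"))
    K <- num / (F * Pfree)
  }
  list(lnK = log(K * cfg$c_std), K = K, reason = NA_character_)
}

# Shared driver: evaluate lnK over a weight series with per-point
# exclusion and first-order Gaussian error propagation.
k_series_for <- function(w, cfg, transition) {
  stopifnot(inherits(w, "weight_series"))
  if (any(w$phi_I + w$phi_S > 100 * cfg$Pt / cfg$Lt + 1e-9)) {
    stop("bound ligand exceeds total protein: inconsistent configuration")
  }
  n <- nrow(w)
  lnK <- K <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- lnK_point(c(w$phi_F[i], w$phi_I[i], w$phi_S[i]), cfg, transition)
    lnK[i] <- p$lnK; K[i] <- p$K; reason[i] <- p$reason
  }
  keep <- is.na(reason)
  sigma <- propagate_weight_errors(w, cfg, transition)
  excluded <- data.frame(temperature_C = w$temperature_C[!keep],
                         reason = reason[!keep])
  new_k_series(transition, w$temperature_C[keep], lnK[keep], K[keep],
               sigma[keep], excluded)
}

#' Binding constant of the total-binding transition (F-T)
#'
#' Mass-action constant `K = [T] / ([F] (Pt - [T]))` with `[T] = [I]+[S]`,
#' in L/mol; `lnK` is taken on `K * c_std`. Points with vanishing free
#' ligand or vanishing bound fraction are excluded with a recorded reason
#' rather than raising an error.
#'
#' @param w A [weight_series()].
#' @param cfg An [experiment_config()].
#' @return A `k_series` data.frame (columns `temperature_C`, `inv_T_K`,
#'   `lnK`, `sigma_lnK`, `K`), with attributes `transition` and
#'   `excluded_points`.
#' @export
k_total <- function(w, cfg) k_series_for(w, cfg, "F-T")

#' Binding constant of the interconversion transition (I-S)
#'
#' `K = phi_S / phi_I`, dimensionless (no standard-concentration factor).
#' Points with either weight zero are excluded with a reason.
#'
#' @inheritParams k_total
#' @return A `k_series` data.frame.
#' @export
k_interconversion <- function(w, cfg = experiment_config(Pt = 1)) {
  k_series_for(w, cfg, "I-S")
}

#' Binding constants of the coupled individual transitions (F-I, F-S)
#'
#' Under the 1:1 coupled model with intermediately and strongly bound
#' ligands on different protein molecules, the free protein available to
#' either transition is `Pt - [I] - [S]`, giving
#' `K_F-I = [I] / ([F] (Pt - [I] - [S]))` and
#' `K_F-S = [S] / ([F] (Pt - [I] - [S]))` (L/mol). When the co-appearing
#' state is unpopulated this reduces exactly to the total-binding form
#' with `[T]` replaced by the single bound species.
#'
#' @inheritParams k_total
#' @param which Transition, "F-I" or "F-S".
#' @return A `k_series` data.frame.
#' @export
k_coupled <- function(w, cfg, which = c("F-I", "F-S")) {
  which <- match.arg(which)
  k_series_for(w, cfg, which)
}

#' Propagate weight errors into lnK errors
#'
#' First-order Gaussian propagation of the per-temperature weight error
#' `sigma_phi` (applied independently to phi_F, phi_I and phi_S) through
#' the mass-action expressions, using a central-difference Jacobian with
#' step 0.01 percentage points.
#'
#' @inheritParams k_total
#' @param transition One of "F-I", "F-S", "F-T", "I-S".
#' @return Numeric vector of `sigma_lnK`, one per temperature (NA at
#'   points where the transition is undefined).
#' @export
propagate_weight_errors <- function(w, cfg,
                                    transition = c("F-I", "F-S", "F-T", "I-S")) {
  transition <- match.arg(transition)
  stopifnot(inherits(w, "weight_series"))
  h <- 0.01
  vapply(seq_len(nrow(w)), function(i) {
    phi <- c(w$phi_F[i], w$phi_I[i], w$phi_S[i])
    if (!is.na(lnK_point(phi, cfg, transition)$reason)) return(NA_real_)
    s <- w$sigma_phi[i]
    if (s == 0) return(0)
    grad <- vapply(1:3, function(j) {
      up <- phi; up[j] <- up[j] + h
      dn <- phi; dn[j] <- dn[j] - h
      a <- lnK_point(up, cfg, transition)
      b <- lnK_point(dn, cfg, transition)
      if (!is.na(a$reason) || !is.na(b$reason)) return(NA_real_)
      (a$lnK - b$lnK) / (2 * h)
    }, numeric(1))
    sqrt(sum((grad * s)^2, na.rm = TRUE))
  }, numeric(1))
}

#' Solve the coupled 1:1 system for given binding constants
#'
#' Inverts the coupled mass-action model at one temperature: given
#' `K_FI` and `K_FS` (L/mol), finds the equilibrium concentrations from the
#' positive root of the quadratic
#' `kappa f^2 + f (1 + kappa (Pt - Lt)) - Lt = 0` in the free-ligand
#' concentration `f`, with `kappa = K_FI + K_FS`.
#'
#' @param K_FI,K_FS Association constants in L/mol (>= 0).
#' @param cfg An [experiment_config()].
#' @return Named list with `F`, `I`, `S`, `P_free` (mol/L).
#' @export
solve_forward <- function(K_FI, K_FS, cfg) {
  stopifnot(K_FI >= 0, K_FS >= 0)
  Pt <- cfg$Pt; Lt <- cfg$Lt
  kap <- K_FI + K_FS
  if (kap == 0) {
    return(list(F = Lt, I = 0, S = 0, P_free = Pt))
  }
  b <- 1 + kap * (Pt - Lt)
  disc <- b^2 + 4 * kap * Lt
  if (disc < 0) stop("internal error: negative discriminant")
  f <- (-b + sqrt(disc)) / (2 * kap)
  bound <- Lt - f
  Pfree <- Pt - bound
  I <- K_FI * f * Pfree
  S <- K_FS * f * Pfree
  list(F = f, I = I, S = S, P_free = Pfree)
}

#' Constant-heat-capacity van't Hoff law
#'
#' Parameter set describing a transition's true thermodynamics for
#' scenario generation: `lnK(T) = -dH(T)/(R T) + dS(T)/R` with
#' `dH(T) = dH_ref + dCp (T - T_ref)` and
#' `dS(T) = dS_ref + dCp ln(T / T_ref)`. `dCp = 0` gives the classic
#' linear van't Hoff line in 1/T.
#'
#' @param dH_ref Reference enthalpy change, J/mol.
#' @param dS_ref Reference entropy change, J/(mol K).
#' @param dCp Heat-capacity change, J/(mol K) (default 0).
#' @param T_ref Reference temperature, K (default 310.15).
#' @return Object of class `vh_law`.
#' @export
vh_law <- function(dH_ref, dS_ref, dCp = 0, T_ref = 310.15) {
  structure(list(dH_ref = dH_ref, dS_ref = dS_ref, dCp = dCp, T_ref = T_ref),
            class = "vh_law")
}

#' Evaluate a van't Hoff law
#'
#' @param law A [vh_law()].
#' @param temp_C Temperatures in degC.
#' @return Dimensionless lnK (standard-state convention).
#' @export
eval_vh_law <- function(law, temp_C) {
  stopifnot(inherits(law, "vh_law"))
  TK <- as_kelvin(temp_C)
  dH <- law$dH_ref + law$dCp * (TK - law$T_ref)
  dS <- law$dS_ref + law$dCp * log(TK / law$T_ref)
  -dH / (R_GAS * TK) + dS / R_GAS
}

#' Generate a synthetic weight series from known thermodynamics
#'
#' Evaluates the true `K_FI(T)` and `K_FS(T)` from the supplied laws,
#' solves the coupled equilibrium exactly at each grid temperature,
#' converts concentrations to component weights, and adds truncated
#' Gaussian noise (clipped at 0, triples renormalized to 100). The
#' noiseless truth is attached for recovery tests.
#'
#' @param law_FI,law_FS [vh_law()] objects for the two individual
#'   transitions (lnK refers to K in L/mol times the standard
#'   concentration).
#' @param cfg An [experiment_config()]; temperatures must lie inside the
#'   modelled range 0-90 degC.
#' @param sigma_phi Weight noise SD in percentage points (also recorded as
#'   the error column).
#' @param seed Integer seed; NULL for the current RNG stream.
#' @return A [weight_series()] with attributes `truth` (noiseless
#'   weight_series) and `truth_lnK` (data.frame of generating lnK per
#'   transition).
#' @export
generate_scenario <- function(law_FI, law_FS, cfg, sigma_phi = 0,
                              seed = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  tc <- cfg$temperatures
  if (any(tc < 0 | tc > 90)) stop("temperature grid must lie within 0-90 degC")
  K_FI <- exp(eval_vh_law(law_FI, tc)) / cfg$c_std
  K_FS <- exp(eval_vh_law(law_FS, tc)) / cfg$c_std
  conc <- lapply(seq_along(tc), function(i) solve_forward(K_FI[i], K_FS[i], cfg))
  phi <- vapply(conc, function(x) {
    100 * c(x$F, x$I, x$S) / cfg$Lt
  }, numeric(3))
  truth <- weight_series(tc, phi[1, ], phi[2, ], phi[3, ], sigma_phi = 0)
  noisy <- phi
  if (sigma_phi > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    noisy <- pmax(phi + stats::rnorm(length(phi), sd = sigma_phi), 0)
    noisy <- apply(noisy, 2, function(p) 100 * p / sum(p))
  }
  # renormalized triples satisfy the weight_series invariants exactly
  out <- weight_series(tc, noisy[1, ], noisy[2, ], noisy[3, ],
                       sigma_phi = sigma_phi)
  attr(out, "truth") <- truth
  attr(out, "truth_lnK") <- data.frame(
    temperature_C = tc,
    lnK_FI = log(K_FI * cfg$c_std),
    lnK_FS = log(K_FS * cfg$c_std),
    lnK_IS = log(K_FS / K_FI),
    lnK_FT = log((K_FI + K_FS) * cfg$c_std))
  out
}

#' Read / write weight-series CSV
#'
#' CSV with header `temperature_C, phi_F, phi_I, phi_S, sigma_phi`.
#'
#' @param path File path.
#' @return `read_weight_series()` returns a [weight_series()].
#' @export
read_weight_series <- function(path) {
  d <- utils::read.csv(path)
  need <- c("temperature_C", "phi_F", "phi_I", "phi_S", "sigma_phi")
  if (!all(need %in% names(d))) {
    stop("weight CSV must have columns: ", paste(need, collapse = ", "))
  }
  d <- d[order(d$temperature_C), ]
  weight_series(d$temperature_C, d$phi_F, d$phi_I, d$phi_S, d$sigma_phi)
}

#' @rdname read_weight_series
#' @param w A [weight_series()] to write.
#' @export
write_weight_series <- function(w, path) {
  stopifnot(inherits(w, "weight_series"))
  utils::write.csv(as.data.frame(w), path, row.names = FALSE)
  invisible(path)
}

#' Write a k_series CSV
#'
#' One row per retained temperature: `temperature_C`, `inv_T_K`, `lnK`,
#' `sigma_lnK`, `K_L_per_mol`, `KD_mol_per_L`.
#'
#' @param ks A `k_series`.
#' @param path File path.
#' @export
write_k_series <- function(ks, path) {
  stopifnot(inherits(ks, "k_series"))
  d <- data.frame(temperature_C = ks$temperature_C, inv_T_K = ks$inv_T_K,
                  lnK = ks$lnK, sigma_lnK = ks$sigma_lnK,
                  K_L_per_mol = ks$K, KD_mol_per_L = 1 / ks$K)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
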