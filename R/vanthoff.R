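# Weighted fitting of lnK vs 1/T: parametrized model families (polynomials,
# Boltzmann sigmoid, exponential), the classic linear and constant-dCp
# van't Hoff forms, chi-squared model selection with an oscillation screen,
# and refit-based error bands.
#
# The fit variable is x = 1/T (K^-1) throughout; y = lnK. Points are
# weighted by 1/sigma_lnK^2, falling back to unit weights when all sigma
# are zero. All initializations are closed-form functions of the data, so
# every fit is deterministic.

#' Model family descriptor
#'
#' @param kind One of `"poly2"` .. `"poly6"`, `"boltzmann"`,
#'   `"exponential"`, `"linear_vh"`, `"const_cp_vh"`.
#' @return Object of class `model_family` with elements `kind` and
#'   `n_params`.
#' @export
model_family <- function(kind) {
  kinds <- c(paste0("poly", 2:6), "boltzmann", "exponential",
             "linear_vh", "const_cp_vh")
  kind <- match.arg(kind, kinds)
  n <- switch(kind,
              boltzmann = 4L, exponential = 3L, linear_vh = 2L,
              const_cp_vh = 3L,
              as.integer(substring(kind, 5)) + 1L)
  structure(list(kind = kind, n_params = n), class = "model_family")
}

#' Default candidate families for model selection
#'
#' Polynomials of order 2-4, the Boltzmann sigmoid and the exponential.
#' Higher polynomial orders (5, 6) are available but opt-in, since
#' over-parametrized fits readily produce surplus extrema and zero
#' crossings inside the data range.
#'
#' @return List of [model_family()] objects.
#' @export
default_families <- function() {
  lapply(c("poly2", "poly3", "poly4", "boltzmann", "exponential"),
         model_family)
}


# vcov of an lm fit without the spurious "essentially perfect fit" warning
# that summary.lm emits on exact synthetic data.
lm_vcov <- function(fit) {
  withCallingHandlers(stats::vcov(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

fit_weights <- function(series) {
  s <- series$sigma_lnK
  if (is.null(s) || all(!is.finite(s)) || all(s == 0, na.rm = TRUE)) {
    rep(1, nrow(series))
  } else {
    s <- ifelse(!is.finite(s) | s <= 0, min(s[s > 0], na.rm = TRUE), s)
    1 / s^2
  }
}

new_vh_fit <- function(family, coefficients, vcov, chi2_red, domain,
                       converged = TRUE, T_ref = NULL) {
  structure(list(family = family, coefficients = coefficients, vcov = vcov,
                 chi2_red = chi2_red, domain = domain, converged = converged,
                 T_ref = T_ref, band_fits = NULL),
            class = "vh_fit")
}

#' @export
print.vh_fit <- function(x, ...) {
  cat(sprintf("<vh_fit> family %s%s, chi2_red = %.4g, domain 1/T = [%.6g, %.6g]\n",
              x$family$kind, if (x$converged) "" else " (NOT converged)",
              x$chi2_red, x$domain[1], x$domain[2]))
  print(x$coefficients)
  if (!is.null(x$band_fits)) cat("with upper/lower band fits\n")
  invisible(x)
}

boltzmann_fn <- function(x, A1, A2, x0, dx) {
  A2 + (A1 - A2) / (1 + exp((x - x0) / dx))
}

# Closed-form, data-derived starting values for the Boltzmann sigmoid:
# plateaus from the terminal y values (ordered in x), x0 from the x at
# which y crosses the midpoint, dx from the span/10.
boltzmann_start <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  A1 <- y[1]; A2 <- y[length(y)]
  mid <- (A1 + A2) / 2
  x0 <- x[which.min(abs(y - mid))]
  dx <- diff(range(x)) / 10
  if (dx == 0) dx <- 1e-6
  list(A1 = A1, A2 = A2, x0 = x0, dx = dx)
}

# Deterministic starting values for y = y0 + A exp(R0 x): estimate R0 from
# the log-ratio of successive differences at the data ends, fall back to
# +/- 2/span scanned over a fixed small set if degenerate.
exponential_start <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  n <- length(x)
  span <- diff(range(x))
  d1 <- y[2] - y[1]
  d2 <- y[n] - y[n - 1]
  r <- NA_real_
  if (is.finite(d1) && is.finite(d2) && d1 * d2 > 0 && abs(d1) > 0) {
    r <- log(abs(d2 / d1)) / (mean(x[c(n - 1, n)]) - mean(x[1:2]))
  }
  if (!is.finite(r) || r == 0) r <- 2 / span
  A <- (y[n] - y[1]) / (exp(r * x[n]) - exp(r * x[1]))
  if (!is.finite(A) || A == 0) A <- stats::sd(y)
  y0 <- mean(y - A * exp(r * x))
  list(y0 = y0, A = A, R0 = r)
}

#' Fit one model family to a van't Hoff series
#'
#' Weighted least squares of `lnK` on `x = 1/T`. Polynomial families use a
#' linear fit; the Boltzmann sigmoid
#' `y = A2 + (A1 - A2)/(1 + exp((x - x0)/dx))` and the exponential
#' `y = y0 + A exp(R0 x)` use Levenberg-Marquardt with fixed, data-derived
#' starting values. Non-convergence returns a fit flagged
#' `converged = FALSE` instead of an error.
#'
#' @param series A `k_series` (or any data.frame with `inv_T_K`, `lnK`,
#'   `sigma_lnK`).
#' @param family A [model_family()] or its kind string.
#' @return A `vh_fit` with coefficients, covariance, weighted reduced
#'   chi-squared and the fitted 1/T domain.
#' @export
fit_model <- function(series, family) {
  if (is.character(family)) family <- model_family(family)
  x <- series$inv_T_K
  y <- series$lnK
  w <- fit_weights(series)
  n <- length(x)
  if (n < family$n_params + 2L) {
    stop("need at least n_params + 2 retained points")
  }
  kind <- family$kind
  domain <- range(x)
  chi2_of <- function(res) sum(w * res^2) / (n - family$n_params)

  if (grepl("^poly", kind)) {
    deg <- as.integer(substring(kind, 5))
    X <- stats::poly(x, degree = deg, raw = TRUE)
    fit <- stats::lm(y ~ X, weights = w)
    cf <- stats::coef(fit)
    names(cf) <- paste0("c", 0:deg)
    return(new_vh_fit(family, cf, lm_vcov(fit),
                      chi2_of(stats::resid(fit)), domain))
  }
  if (kind == "linear_vh") return(fit_linear_vh(series)$fit)
  if (kind == "const_cp_vh") return(fit_const_cp_vh(series)$fit)

  df <- data.frame(x = x, y = y)
  fml <- if (kind == "boltzmann") {
    y ~ A2 + (A1 - A2) / (1 + exp((x - x0) / dx))
  } else {
    y ~ y0 + A * exp(R0 * x)
  }
  start <- if (kind == "boltzmann") boltzmann_start(x, y) else exponential_start(x, y)
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = df, start = start, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_vh_fit(family,
                      stats::setNames(rep(NA_real_, family$n_params),
                                      names(start)),
                      NULL, Inf, domain, converged = FALSE))
  }
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  new_vh_fit(family, stats::coef(fit), vc, chi2_of(stats::resid(fit)), domain)
}

#' Evaluate a fitted van't Hoff model
#'
#' @param fit A `vh_fit`.
#' @param x Values of 1/T (K^-1).
#' @param deriv Derivative order with respect to x: 0, 1 or 2 (analytic
#'   for every built-in family).
#' @return Numeric vector.
#' @export
eval_vh_fit <- function(fit, x, deriv = 0L) {
  stopifnot(inherits(fit, "vh_fit"))
  cf <- fit$coefficients
  kind <- fit$family$kind
  if (grepl("^poly", kind) || kind == "linear_vh" || kind == "const_cp_vh") {
    if (kind == "linear_vh") {
      p <- c(cf[["a"]], cf[["b"]])          # y = a + b x
    } else if (kind == "const_cp_vh") {
      # lnK(x) linear combination; expand to pseudo-polynomial + log term
      return(eval_const_cp(cf, fit$T_ref, x, deriv))
    } else {
      p <- as.numeric(cf)                    # c0 + c1 x + ...
    }
    deg <- length(p) - 1L
    pow <- 0:deg
    coefs <- p
    for (k in seq_len(deriv)) {
      coefs <- coefs * pow
      pow <- pmax(pow - 1L, 0L)
    }
    return(as.numeric(vapply(x, function(xx) sum(coefs * xx^pow), numeric(1))))
  }
  if (kind == "boltzmann") {
    A1 <- cf[["A1"]]; A2 <- cf[["A2"]]; x0 <- cf[["x0"]]; dx <- cf[["dx"]]
    e <- exp((x - x0) / dx)
    if (deriv == 0L) return(A2 + (A1 - A2) / (1 + e))
    if (deriv == 1L) return(-(A1 - A2) * e / (dx * (1 + e)^2))
    return(-(A1 - A2) * e * (1 - e) / (dx^2 * (1 + e)^3))
  }
  # exponential
  y0 <- cf[["y0"]]; A <- cf[["A"]]; R0 <- cf[["R0"]]
  if (deriv == 0L) return(y0 + A * exp(R0 * x))
  A * R0^deriv * exp(R0 * x)
}

# lnK(x) for the constant-dCp form in x = 1/T:
# lnK = -(dH_ref - dCp*T_ref)/R * x + (dS_ref - dCp)/R - (dCp/R) ln(T_ref x)
eval_const_cp <- function(cf, T_ref, x, deriv = 0L) {
  dH <- cf[["dH_ref"]]; dS <- cf[["dS_ref"]]; dCp <- cf[["dCp"]]
  a <- -(dH - dCp * T_ref) / R_GAS
  if (deriv == 0L) {
    a * x + (dS - dCp) / R_GAS - (dCp / R_GAS) * log(T_ref * x)
  } else if (deriv == 1L) {
    a - dCp / (R_GAS * x)
  } else {
    dCp / (R_GAS * x^2)
  }
}

#' Classic linear van't Hoff fit
#'
#' Weighted straight line `lnK = -(dH/R) (1/T) + dS/R`, giving
#' temperature-independent enthalpy and entropy changes.
#'
#' @param series A `k_series`.
#' @return List with `dH` (J/mol), `dS` (J/(mol K)), their standard errors
#'   `se_dH`, `se_dS`, and `fit` (a `vh_fit` of kind `linear_vh` with
#'   coefficients `a` (intercept) and `b` (slope)).
#' @export
fit_linear_vh <- function(series) {
  x <- series$inv_T_K; y <- series$lnK
  if (length(x) < 3L) stop("need at least 3 points")
  w <- fit_weights(series)
  fit <- stats::lm(y ~ x, weights = w)
  cf <- stats::setNames(stats::coef(fit), c("a", "b"))
  se <- sqrt(diag(lm_vcov(fit)))
  fam <- model_family("linear_vh")
  vf <- new_vh_fit(fam, cf, lm_vcov(fit),
                   sum(w * stats::resid(fit)^2) / (length(x) - 2L), range(x))
  list(dH = -R_GAS * cf[["b"]], dS = R_GAS * cf[["a"]],
       se_dH = R_GAS * se[2], se_dS = R_GAS * se[1], fit = vf)
}

#' Constant heat-capacity van't Hoff fit
#'
#' Fits `lnK(T) = -(dH_ref + dCp (T - T_ref))/(R T) +
#' (dS_ref + dCp ln(T/T_ref))/R`, which is linear in the parameters
#' `(dH_ref, dS_ref, dCp)`, by weighted least squares. With `dCp` frozen
#' at 0 the design reduces exactly to the linear van't Hoff fit.
#'
#' @param series A `k_series`.
#' @param T_ref Reference temperature in K (default 310.15).
#' @param fix_dCp Optionally freeze dCp at a fixed value (0 reduces the
#'   model exactly to the linear van't Hoff fit).
#' @return List with `dH_ref` (J/mol), `dS_ref` (J/(mol K)), `dCp`
#'   (J/(mol K)), standard errors `se_dH_ref`, `se_dS_ref`, `se_dCp`, and
#'   `fit` (a `vh_fit` of kind `const_cp_vh`).
#' @export
fit_const_cp_vh <- function(series, T_ref = 310.15, fix_dCp = NULL) {
  x <- series$inv_T_K; y <- series$lnK
  if (length(x) < 4L) stop("need at least 4 points")
  TK <- 1 / x
  w <- fit_weights(series)
  # basis functions of (dH_ref, dS_ref, dCp)
  f1 <- -1 / (R_GAS * TK)
  f2 <- rep(1 / R_GAS, length(TK))
  f3 <- (T_ref / TK - 1 + log(TK / T_ref)) / R_GAS
  if (is.null(fix_dCp)) {
    fit <- stats::lm(y ~ 0 + f1 + f2 + f3, weights = w)
    cf <- stats::setNames(stats::coef(fit), c("dH_ref", "dS_ref", "dCp"))
    se <- sqrt(diag(lm_vcov(fit)))
    vc <- lm_vcov(fit)
    npar <- 3L
  } else {
    yr <- y - fix_dCp * f3
    fit <- stats::lm(yr ~ 0 + f1 + f2, weights = w)
    cf <- stats::setNames(c(stats::coef(fit), fix_dCp),
                          c("dH_ref", "dS_ref", "dCp"))
    se <- c(sqrt(diag(lm_vcov(fit))), 0)
    vc <- lm_vcov(fit)
    npar <- 2L
  }
  fam <- model_family("const_cp_vh")
  vf <- new_vh_fit(fam, cf, vc,
                   sum(w * stats::resid(fit)^2) / (length(x) - npar),
                   range(x), T_ref = T_ref)
  list(dH_ref = cf[["dH_ref"]], dS_ref = cf[["dS_ref"]], dCp = cf[["dCp"]],
       se_dH_ref = se[1], se_dS_ref = se[2], se_dCp = se[3], fit = vf)
}

# Count sign changes of the fitted first derivative on a fine grid inside
# the data range (the oscillation/artifact screen).
derivative_sign_changes <- function(fit, n_grid = 512L) {
  xg <- seq(fit$domain[1], fit$domain[2], length.out = n_grid)
  d <- eval_vh_fit(fit, xg, deriv = 1L)
  s <- sign(d)
  s <- s[s != 0]
  sum(diff(s) != 0)
}

#' Select the best-fitting model family
#'
#' Fits every candidate, drops non-converged fits and fits whose first
#' derivative changes sign more than `max_sign_changes` times inside the
#' data range (an over-parametrization artifact screen), then picks the
#' lowest weighted reduced chi-squared; candidates whose chi-squared lies
#' within the tie window of the minimum are resolved toward fewer
#' parameters. The default window is adaptive: one relative standard
#' deviation of a reduced chi-squared at the best fit's degrees of
#' freedom, `sqrt(2/dof)` (floored at 1%), so statistically
#' indistinguishable fits resolve to the simplest model. If everything is
#' rejected, falls back to the linear van't Hoff fit with a warning.
#'
#' @param series A `k_series`.
#' @param candidates List of [model_family()] objects (default
#'   [default_families()]).
#' @param max_sign_changes Maximum allowed derivative sign changes
#'   (default 4).
#' @param tie Tie window as a fraction of the minimum chi-squared, or
#'   `"adaptive"` (default).
#' @return The winning `vh_fit`.
#' @export
select_model <- function(series, candidates = default_families(),
                         max_sign_changes = 4L, tie = "adaptive") {
  fits <- lapply(candidates, function(fam) {
    tryCatch(fit_model(series, fam), error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && f$converged && is.finite(f$chi2_red),
                 fits)
  fits <- Filter(function(f) derivative_sign_changes(f) <= max_sign_changes,
                 fits)
  if (length(fits) == 0L) {
    warning("all candidate fits rejected; falling back to linear van't Hoff")
    return(fit_linear_vh(series)$fit)
  }
  chi2 <- vapply(fits, function(f) f$chi2_red, numeric(1))
  npar <- vapply(fits, function(f) f$family$n_params, integer(1))
  best_chi2 <- min(chi2)
  tie_frac <- if (identical(tie, "adaptive")) {
    dof_best <- nrow(series) - npar[which.min(chi2)]
    max(0.01, sqrt(2 / max(dof_best, 1L)))
  } else {
    as.numeric(tie)
  }
  tied <- which(chi2 <= best_chi2 * (1 + tie_frac))
  # among near-ties prefer fewer parameters, then lower chi2 (stable under
  # candidate reordering)
  pick <- tied[order(npar[tied], chi2[tied])][1]
  fits[[pick]]
}

#' Fit error-band curves
#'
#' Refits the chosen family to the shifted point sets `lnK + sigma_lnK`
#' and `lnK - sigma_lnK`; the two fitted curves are the error band. If
#' either band fit fails to converge the bands are omitted with a warning.
#'
#' @param series A `k_series` with `sigma_lnK`.
#' @param fit The central `vh_fit`.
#' @return `fit` with `band_fits = list(upper =, lower =)` attached (or
#'   unchanged on failure).
#' @export
fit_error_bands <- function(series, fit) {
  stopifnot(inherits(fit, "vh_fit"))
  up <- series; up$lnK <- series$lnK + series$sigma_lnK
  lo <- series; lo$lnK <- series$lnK - series$sigma_lnK
  fu <- tryCatch(fit_model(up, fit$family), error = function(e) NULL)
  fl <- tryCatch(fit_model(lo, fit$family), error = function(e) NULL)
  if (is.null(fu) || is.null(fl) || !fu$converged || !fl$converged) {
    warning("band fit did not converge; bands omitted")
    return(fit)
  }
  fit$band_fits <- list(upper = fu, lower = fl)
  fit
}

#' Serialize a fit report to structured text
#'
#' @param fit A `vh_fit`.
#' @param path Output file.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "vh_fit"))
  fmt <- function(f, tag) c(
    sprintf("%sfamily: %s", tag, f$family$kind),
    sprintf("%schi2_red: %.10g", tag, f$chi2_red),
    sprintf("%sdomain_invT: %.10g %.10g", tag, f$domain[1], f$domain[2]),
    sprintf("%scoef_%s: %.10g", tag, names(f$coefficients), f$coefficients))
  out <- fmt(fit, "")
  if (!is.null(fit$band_fits)) {
    out <- c(out, fmt(fit$band_fits$upper, "upper_"),
             fmt(fit$band_fits$lower, "lower_"))
  }
  writeLines(out, path)
  invisible(path)
}
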