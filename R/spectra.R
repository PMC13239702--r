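# Parametric nitroxide CW EPR lineshapes and spectral decomposition.
#
# A nitroxide spin probe gives a three-line (14N hyperfine) first-derivative
# spectrum. Each dynamic species (free F, intermediately attached I, strongly
# pocket-bound S) contributes one sub-spectrum; the composite spectrum is a
# weighted sum and the weights are the quantities all downstream
# thermodynamics is built on. Lines are modelled as first-derivative
# pseudo-Voigt profiles with an mI-dependent peak-to-peak width
# dB(mI) = A + B*mI + C*mI^2; rotational broadening enters through these
# width coefficients rather than through an explicit slow-motional theory.

#' EPR spectrum object
#'
#' A first-derivative continuous-wave EPR spectrum: a strictly increasing,
#' uniformly spaced magnetic-field axis (mT) with intensity values in
#' arbitrary units, recorded at one temperature.
#'
#' @param field Numeric vector of magnetic-field values in mT, strictly
#'   increasing with (numerically) constant step, length >= 3.
#' @param intensity Numeric vector of first-derivative amplitudes, same
#'   length as `field`.
#' @param temperature Temperature in degrees Celsius.
#' @return An object of class `epr_spectrum` (list with elements `field`,
#'   `intensity`, `temperature`).
#' @export
epr_spectrum <- function(field, intensity, temperature = NA_real_) {
  field <- as.numeric(field)
  intensity <- as.numeric(intensity)
  if (length(field) < 3L) stop("field axis needs at least 3 points")
  if (length(field) != length(intensity)) {
    stop("field and intensity must have equal length")
  }
  d <- diff(field)
  if (any(d <= 0)) stop("field axis must be strictly increasing")
  if (diff(range(d)) > 1e-6 * mean(d)) {
    stop("field axis must have a uniform step")
  }
  structure(list(field = field, intensity = intensity,
                 temperature = as.numeric(temperature)[1]),
            class = "epr_spectrum")
}

#' @export
print.epr_spectrum <- function(x, ...) {
  cat(sprintf("<epr_spectrum> %d points, %.4g-%.4g mT, T = %s degC\n",
              length(x$field), min(x$field), max(x$field),
              format(x$temperature)))
  invisible(x)
}

#' Default magnetic-field axis
#'
#' The measurement window used throughout: 332.5 to 342.5 mT sampled at
#' 4096 points (X band, nitroxide centre field about 337.5 mT).
#'
#' @param n Number of points.
#' @return Numeric vector of field values (mT).
#' @export
default_field_axis <- function(n = 4096L) {
  seq(332.5, 342.5, length.out = n)
}

#' Spectral component parameters
#'
#' Parameters of one dynamic species' nitroxide triplet: isotropic 14N
#' hyperfine splitting `a_iso` (mT, sensor of local polarity), rotational
#' correlation time `tau_c` (s, descriptor of mobility; its broadening is
#' expressed through the width coefficients), peak-to-peak linewidth
#' coefficients `width_coeffs` = (A, B, C) in mT for
#' dB(mI) = A + B*mI + C*mI^2, and the Lorentzian/Gaussian mixing fraction
#' `eta` (1 = pure Lorentzian).
#'
#' @param label One of "F", "I", "S".
#' @param a_iso Hyperfine splitting in mT, > 0.
#' @param tau_c Rotational correlation time in s, > 0.
#' @param width_coeffs Numeric length-3 vector (A, B, C) in mT; the implied
#'   widths at mI = -1, 0, +1 must all be positive.
#' @param eta Mixing fraction in [0, 1].
#' @return Object of class `component_params`.
#' @export
component_params <- function(label, a_iso, tau_c, width_coeffs, eta = 1) {
  label <- match.arg(label, c("F", "I", "S"))
  stopifnot(length(width_coeffs) == 3L)
  if (!is.finite(a_iso) || a_iso <= 0) stop("a_iso must be > 0")
  if (!is.finite(tau_c) || tau_c <= 0) stop("tau_c must be > 0")
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  w <- linewidth(width_coeffs, c(-1, 0, 1))
  if (any(w <= 0)) stop("width dB(mI) must be positive for mI in {-1,0,+1}")
  structure(list(label = label, a_iso = a_iso, tau_c = tau_c,
                 width_coeffs = as.numeric(width_coeffs), eta = eta),
            class = "component_params")
}

#' Peak-to-peak linewidth at a given nuclear spin projection
#'
#' @param width_coeffs Numeric (A, B, C) in mT.
#' @param mI Nuclear spin projection(s), in {-1, 0, +1}.
#' @return dB(mI) = A + B*mI + C*mI^2 in mT.
#' @export
linewidth <- function(width_coeffs, mI) {
  width_coeffs[1] + width_coeffs[2] * mI + width_coeffs[3] * mI^2
}

# First-derivative pseudo-Voigt line with unit absorption area, centred at
# x0 with peak-to-peak width dBpp. Gaussian: sd = dBpp/2; Lorentzian:
# HWHM = sqrt(3)/2 * dBpp (derivative extrema of a Lorentzian sit at
# +/- gamma/sqrt(3)).
deriv_pseudo_voigt <- function(x, x0, dBpp, eta) {
  u <- x - x0
  sd <- dBpp / 2
  g <- -u / (sqrt(2 * pi) * sd^3) * exp(-u^2 / (2 * sd^2))
  gam <- sqrt(3) / 2 * dBpp
  l <- -(2 / pi) * gam * u / (u^2 + gam^2)^2
  eta * l + (1 - eta) * g
}

#' Render one spectral component
#'
#' Sums three first-derivative pseudo-Voigt lines at the hyperfine line
#' positions `center_field - a_iso * mI`, mI in {+1, 0, -1}, each with its
#' mI-dependent peak-to-peak width, and normalizes the result to unit
#' double integral (cumulative trapezoid applied twice; the final value of
#' the running double integral is 1).
#'
#' @param params A [component_params()] object.
#' @param field Field axis (mT); must span all three line centres.
#' @param center_field Centre field in mT (default 337.5, the midpoint of
#'   the default sweep).
#' @param temperature Temperature tag for the returned spectrum (degC).
#' @return An [epr_spectrum()].
#' @export
render_component <- function(params, field = default_field_axis(),
                             center_field = 337.5,
                             temperature = NA_real_) {
  stopifnot(inherits(params, "component_params"))
  mI <- c(1, 0, -1)
  centers <- center_field - params$a_iso * mI
  if (any(centers < min(field)) || any(centers > max(field))) {
    stop("line centre outside the field axis")
  }
  w <- linewidth(params$width_coeffs, mI)
  if (any(w <= 0)) stop("non-positive linewidth")
  y <- rowSums(vapply(seq_along(mI), function(i) {
    deriv_pseudo_voigt(field, centers[i], w[i], params$eta)
  }, numeric(length(field))))
  s <- epr_spectrum(field, y, temperature)
  normalize_spectrum(s)
}

# Running double integral (cumtrapz twice) of a spectrum's intensity.
double_integral <- function(spectrum) {
  i1 <- pracma::cumtrapz(spectrum$field, spectrum$intensity)
  i2 <- pracma::cumtrapz(spectrum$field, as.numeric(i1))
  as.numeric(i2)
}

# Scale intensity so the final value of the running double integral is 1.
normalize_spectrum <- function(spectrum) {
  dd <- double_integral(spectrum)
  tot <- dd[length(dd)]
  if (!is.finite(tot) || tot <= 0) stop("cannot normalize: non-positive double integral")
  spectrum$intensity <- spectrum$intensity / tot
  spectrum
}

#' Per-temperature basis of the three component spectra
#'
#' @param F,I,S [epr_spectrum()] objects sharing one field axis, each
#'   normalized to unit double integral (checked to 1e-9).
#' @param temperature Temperature in degC.
#' @return Object of class `component_basis` with elements `temperature`
#'   and `bases` (named list F, I, S).
#' @export
component_basis <- function(F, I, S, temperature = NA_real_) {
  bases <- list(F = F, I = I, S = S)
  for (b in bases) stopifnot(inherits(b, "epr_spectrum"))
  ax <- bases$F$field
  for (b in bases[-1]) {
    if (length(b$field) != length(ax) || max(abs(b$field - ax)) > 1e-9) {
      stop("basis spectra must share one field axis")
    }
  }
  for (nm in names(bases)) {
    dd <- double_integral(bases[[nm]])
    if (abs(dd[length(dd)] - 1) > 1e-9) {
      stop(sprintf("basis %s is not normalized to unit double integral", nm))
    }
  }
  structure(list(temperature = as.numeric(temperature)[1], bases = bases),
            class = "component_basis")
}

#' Default component parameter anchors
#'
#' Representative parameters for the three species at low and high
#' temperature, for use with [interpolate_params()] and
#' [default_basis()]. The free probe is narrow and fast
#' (tau_c ~ 1e-10 s, a_iso ~ 1.6 mT), the intermediately attached probe is
#' broadened (tau_c ~ 1e-9 s), and the strongly bound probe is represented
#' by a powder-like wide triplet (large effective splitting ~ 3.2 mT,
#' broad lines, tau_c ~ 1e-8 s). With increasing temperature tau_c drops
#' and a_iso decreases slightly (less polar environment).
#'
#' @return Named list (F, I, S); each element is a list of
#'   `(temperature, params)` anchors.
#' @export
default_component_anchors <- function() {
  list(
    F = list(
      list(temperature = 0,
           params = component_params("F", a_iso = 1.62, tau_c = 3e-10,
                                     width_coeffs = c(0.12, 0.01, 0.02))),
      list(temperature = 90,
           params = component_params("F", a_iso = 1.58, tau_c = 5e-11,
                                     width_coeffs = c(0.10, 0.005, 0.01)))
    ),
    I = list(
      list(temperature = 0,
           params = component_params("I", a_iso = 1.55, tau_c = 3e-9,
                                     width_coeffs = c(0.28, 0.06, 0.10))),
      list(temperature = 90,
           params = component_params("I", a_iso = 1.50, tau_c = 5e-10,
                                     width_coeffs = c(0.22, 0.04, 0.07)))
    ),
    S = list(
      list(temperature = 0,
           params = component_params("S", a_iso = 3.2, tau_c = 5e-8,
                                     width_coeffs = c(0.9, 0.15, 0.25))),
      list(temperature = 90,
           params = component_params("S", a_iso = 3.0, tau_c = 5e-9,
                                     width_coeffs = c(0.7, 0.12, 0.20)))
    )
  )
}

#' Build the default component basis at a temperature
#'
#' Interpolates the default anchors to `temperature` and renders the three
#' normalized component spectra on a shared axis.
#'
#' @param temperature Temperature in degC (inside the anchor range 0-90).
#' @param field Field axis (mT).
#' @param anchors Anchor set as from [default_component_anchors()].
#' @return A [component_basis()].
#' @export
default_basis <- function(temperature, field = default_field_axis(),
                          anchors = default_component_anchors()) {
  ps <- lapply(anchors, interpolate_params, temperature = temperature)
  component_basis(
    F = render_component(ps$F, field, temperature = temperature),
    I = render_component(ps$I, field, temperature = temperature),
    S = render_component(ps$S, field, temperature = temperature),
    temperature = temperature
  )
}

#' Interpolate component parameters between temperature anchors
#'
#' Piecewise-linear interpolation of `a_iso`, the width coefficients and
#' `eta` in temperature; `tau_c` is interpolated linearly in log10(tau_c).
#' Queries outside the anchor range are rejected (no extrapolation).
#'
#' @param anchors List of anchors, each `list(temperature=, params=)`, with
#'   strictly increasing temperatures (>= 2 anchors).
#' @param temperature Query temperature in degC.
#' @return A [component_params()] at the query temperature.
#' @export
interpolate_params <- function(anchors, temperature) {
  if (length(anchors) < 2L) stop("need at least 2 anchors")
  tt <- vapply(anchors, function(a) a$temperature, numeric(1))
  if (any(diff(tt) <= 0)) stop("anchor temperatures must be strictly increasing")
  if (temperature < tt[1] || temperature > tt[length(tt)]) {
    stop("query temperature outside the anchor range")
  }
  get <- function(f) vapply(anchors, function(a) f(a$params), numeric(1))
  lin <- function(v) stats::approx(tt, v, xout = temperature)$y
  p0 <- anchors[[1]]$params
  component_params(
    label = p0$label,
    a_iso = lin(get(function(p) p$a_iso)),
    tau_c = 10^lin(get(function(p) log10(p$tau_c))),
    width_coeffs = c(lin(get(function(p) p$width_coeffs[1])),
                     lin(get(function(p) p$width_coeffs[2])),
                     lin(get(function(p) p$width_coeffs[3]))),
    eta = lin(get(function(p) p$eta))
  )
}

#' Render a weighted mixture of the basis spectra
#'
#' @param basis A [component_basis()].
#' @param weights Numeric length-3 (F, I, S) in percent; non-negative,
#'   summing to 100 (tolerance 1e-6).
#' @return An [epr_spectrum()] with intensity
#'   `sum(weights/100 * basis intensity)`.
#' @export
render_mixture <- function(basis, weights) {
  stopifnot(inherits(basis, "component_basis"), length(weights) == 3L)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 100) > 1e-6) stop("weights must sum to 100")
  y <- (weights[1] * basis$bases$F$intensity +
        weights[2] * basis$bases$I$intensity +
        weights[3] * basis$bases$S$intensity) / 100
  epr_spectrum(basis$bases$F$field, y, basis$temperature)
}

#' Add Gaussian noise to a spectrum
#'
#' Adds i.i.d. Gaussian noise with standard deviation
#' `sigma_rel * peak-to-peak amplitude`; reproducible for a fixed seed.
#'
#' @param spectrum An [epr_spectrum()].
#' @param sigma_rel Noise SD as a fraction of the peak-to-peak amplitude
#'   (>= 0).
#' @param seed Integer seed; NULL leaves the RNG stream untouched by
#'   seeding.
#' @return The noisy [epr_spectrum()].
#' @export
add_noise <- function(spectrum, sigma_rel, seed = NULL) {
  stopifnot(inherits(spectrum, "epr_spectrum"), sigma_rel >= 0)
  if (sigma_rel == 0) return(spectrum)
  pp <- diff(range(spectrum$intensity))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  spectrum$intensity <- spectrum$intensity +
    stats::rnorm(length(spectrum$intensity), sd = sigma_rel * pp)
  spectrum
}

#' Decompose a spectrum into component weights
#'
#' Non-negative least squares of the spectrum on the three basis spectra
#' ([pracma::lsqnonneg()]), with the coefficients renormalized to weights
#' summing to 100. The residual is reported as RMSD in percent of the
#' spectrum's peak-to-peak amplitude, the same convention used for the
#' weight errors downstream.
#'
#' @param spectrum An [epr_spectrum()] on the basis field axis.
#' @param basis A [component_basis()].
#' @return A list of class `decomposition_result`: `weights` (named F, I,
#'   S, percent), `rmsd` (percent of peak-to-peak), `ill_conditioned`
#'   (logical; TRUE with a warning when the basis condition number exceeds
#'   1e8).
#' @export
decompose_spectrum <- function(spectrum, basis) {
  stopifnot(inherits(spectrum, "epr_spectrum"), inherits(basis, "component_basis"))
  ax <- basis$bases$F$field
  if (length(spectrum$field) != length(ax) ||
      max(abs(spectrum$field - ax)) > 1e-9) {
    stop("spectrum and basis must share one field axis")
  }
  if (all(spectrum$intensity == 0)) stop("all-zero spectrum cannot be decomposed")
  M <- cbind(F = basis$bases$F$intensity,
             I = basis$bases$I$intensity,
             S = basis$bases$S$intensity)
  cn <- kappa(M, exact = TRUE)
  ill <- is.finite(cn) && cn > 1e8
  if (ill) warning("basis is ill-conditioned (condition number > 1e8)")
  fit <- pracma::lsqnonneg(M, spectrum$intensity)
  coef <- pmax(fit$x, 0)
  if (sum(coef) <= 0) stop("degenerate decomposition: all coefficients zero")
  weights <- 100 * coef / sum(coef)
  resid <- spectrum$intensity - as.numeric(M %*% coef)
  pp <- diff(range(spectrum$intensity))
  structure(list(weights = stats::setNames(as.numeric(weights), c("F", "I", "S")),
                 rmsd = 100 * sqrt(mean(resid^2)) / pp,
                 ill_conditioned = ill),
            class = "decomposition_result")
}

#' Read / write two-column ASCII spectra
#'
#' Plain-text spectrum files: two whitespace- or comma-separated columns
#' (field in mT, first-derivative intensity), with an optional
#' `# temperature_C: <value>` header comment.
#'
#' @param path File path.
#' @return `read_spectrum()` returns an [epr_spectrum()];
#'   `write_spectrum()` returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  temp <- NA_real_
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexec("temperature_C:\\s*([-0-9.eE+]+)", hdr))
  for (g in m) if (length(g) == 2L) temp <- as.numeric(g[2])
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  d <- utils::read.table(text = gsub(",", " ", body), header = FALSE,
                         col.names = c("field", "intensity"))
  epr_spectrum(d$field, d$intensity, temp)
}

#' @rdname read_spectrum
#' @param spectrum An [epr_spectrum()] to write.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "epr_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  if (is.finite(spectrum$temperature)) {
    writeLines(sprintf("# temperature_C: %.10g", spectrum$temperature), con)
  }
  writeLines(sprintf("%.15g %.15g", spectrum$field, spectrum$intensity), con)
  invisible(path)
}
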