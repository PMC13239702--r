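# Thermodynamic profiles from fitted van't Hoff curves.
#
# dG(T) = -R T lnK_fit(T)                 [kJ/mol]
# dH(T) = -R d lnK / d(1/T)               [kJ/mol]
# dS(T) = (dH - dG) / T                   [J/(mol K)]
# dCp(T) = d dH / dT                      [kJ/(mol K)]
#
# Enthalpies use the analytic derivative of the fitted model in x = 1/T;
# heat capacities use the analytic second derivative (dCp = R lnK''(x)/T^2).
# By construction dG = dH - T dS holds identically on every profile.

#' Default output temperature grid
#'
#' 0-90 degC in 0.5 K steps, clipped to a fit's 1/T domain when one is
#' supplied. Profile shapes at the domain borders carry the largest
#' fitting uncertainty and features found there are flagged accordingly.
#'
#' @param fit Optional `vh_fit`; the grid is restricted to its domain.
#' @param step Grid step in K (default 0.5).
#' @return Numeric vector of temperatures, degC.
#' @export
default_profile_grid <- function(fit = NULL, step = 0.5) {
  g <- seq(0, 90, by = step)
  if (!is.null(fit)) {
    Tmin <- 1 / fit$domain[2] - 273.15
    Tmax <- 1 / fit$domain[1] - 273.15
    g <- g[g >= Tmin - 1e-9 & g <= Tmax + 1e-9]
  }
  g
}

check_grid_in_domain <- function(fit, grid_C) {
  x <- 1 / as_kelvin(grid_C)
  if (any(x < fit$domain[1] - 1e-12) || any(x > fit$domain[2] + 1e-12)) {
    stop("profile grid extends outside the fitted 1/T domain")
  }
}

#' Gibbs energy profile from a van't Hoff fit
#'
#' @param fit A `vh_fit`.
#' @param grid_C Temperature grid in degC, inside the fitted domain.
#' @return dG in kJ/mol at each grid temperature.
#' @export
gibbs_profile <- function(fit, grid_C = default_profile_grid(fit)) {
  check_grid_in_domain(fit, grid_C)
  TK <- as_kelvin(grid_C)
  -R_GAS * TK * eval_vh_fit(fit, 1 / TK) / 1000
}

#' Enthalpy profile from a van't Hoff fit
#'
#' `dH = -R dlnK/d(1/T)` with the analytic model derivative.
#'
#' @inheritParams gibbs_profile
#' @return dH in kJ/mol.
#' @export
enthalpy_profile <- function(fit, grid_C = default_profile_grid(fit)) {
  check_grid_in_domain(fit, grid_C)
  -R_GAS * eval_vh_fit(fit, 1 / as_kelvin(grid_C), deriv = 1L) / 1000
}

#' Entropy profile
#'
#' `dS = (dH - dG)/T` on aligned grids.
#'
#' @param dG,dH kJ/mol arrays on `grid_C`.
#' @param grid_C Temperature grid, degC.
#' @return dS in J/(mol K).
#' @export
entropy_profile <- function(dG, dH, grid_C) {
  stopifnot(length(dG) == length(grid_C), length(dH) == length(grid_C))
  1000 * (dH - dG) / as_kelvin(grid_C)
}

#' Heat-capacity profile from a van't Hoff fit
#'
#' `dCp = d dH/dT = R lnK''(x) / T^2` with the analytic second derivative
#' of the fitted model in x = 1/T.
#'
#' @inheritParams gibbs_profile
#' @return dCp in kJ/(mol K).
#' @export
heat_capacity_profile <- function(fit, grid_C = default_profile_grid(fit)) {
  check_grid_in_domain(fit, grid_C)
  TK <- as_kelvin(grid_C)
  R_GAS * eval_vh_fit(fit, 1 / TK, deriv = 2L) / TK^2 / 1000
}

profile_quantities <- function(fit, grid_C) {
  dG <- gibbs_profile(fit, grid_C)
  dH <- enthalpy_profile(fit, grid_C)
  data.frame(temperature_C = grid_C,
             dG_kJ_mol = dG,
             dH_kJ_mol = dH,
             dS_J_molK = entropy_profile(dG, dH, grid_C),
             dCp_kJ_molK = heat_capacity_profile(fit, grid_C))
}

#' Full thermodynamic profile for one transition
#'
#' Computes dG, dH, dS and dCp over the grid; when the fit carries band
#' fits (see [fit_error_bands()]), all four quantities are computed
#' independently from the upper and lower band curves and the per-point
#' envelope (min/max of the two) is attached as the error band.
#'
#' @param fit A `vh_fit` (optionally with `band_fits`).
#' @param grid_C Temperature grid in degC (default: 0-90 by 0.5, clipped
#'   to the fitted domain).
#' @param transition Label stored with the profile.
#' @return A data.frame of class `thermo_profile` with columns
#'   `temperature_C`, `dG_kJ_mol`, `dH_kJ_mol`, `dS_J_molK`,
#'   `dCp_kJ_molK`, plus `<q>_lo` / `<q>_hi` band columns when available.
#' @export
thermo_profile <- function(fit, grid_C = default_profile_grid(fit),
                           transition = NA_character_) {
  out <- profile_quantities(fit, grid_C)
  if (!is.null(fit$band_fits)) {
    up <- profile_quantities(fit$band_fits$upper, grid_C)
    lo <- profile_quantities(fit$band_fits$lower, grid_C)
    for (q in c("dG_kJ_mol", "dH_kJ_mol", "dS_J_molK", "dCp_kJ_molK")) {
      out[[paste0(q, "_lo")]] <- pmin(up[[q]], lo[[q]])
      out[[paste0(q, "_hi")]] <- pmax(up[[q]], lo[[q]])
    }
  }
  class(out) <- c("thermo_profile", "data.frame")
  attr(out, "transition") <- transition
  attr(out, "fit") <- fit
  out
}

# Linear interpolation of the root location between bracketing grid points.
interp_zero <- function(t1, t2, v1, v2) t1 - v1 * (t2 - t1) / (v2 - v1)

#' Extract transition features from a profile
#'
#' Zero crossings (sign changes of a quantity, located by linear
#' interpolation between the bracketing grid points) and extrema (sign
#' changes of the discrete first derivative) of dG, dH, dS and dCp.
#' Features within two grid steps of the domain ends are flagged
#' `low_confidence`, since fitted curves are least reliable at the data
#' borders. Also reports the enthalpy-entropy compensation statistic:
#' slope and Pearson correlation of dH against T*dS over the grid (a
#' descriptive statistic, not a mechanistic claim).
#'
#' @param profile A [thermo_profile()].
#' @return List of class `thermo_features`: `zero_crossings` (data.frame
#'   quantity, temperature_C, direction, low_confidence), `extrema`
#'   (data.frame quantity, temperature_C, value, type, low_confidence),
#'   `compensation` (list slope, correlation).
#' @export
extract_features <- function(profile) {
  stopifnot(inherits(profile, "thermo_profile"))
  tc <- profile$temperature_C
  n <- length(tc)
  step <- if (n > 1) tc[2] - tc[1] else NA_real_
  lowconf <- function(temp) {
    temp <= tc[1] + 2 * step + 1e-9 | temp >= tc[n] - 2 * step - 1e-9
  }
  zc <- list(); ex <- list()
  for (q in c("dG_kJ_mol", "dH_kJ_mol", "dS_J_molK", "dCp_kJ_molK")) {
    v <- profile[[q]]
    s <- sign(v)
    ch <- which(s[-n] * s[-1] < 0)
    for (i in ch) {
      t0 <- interp_zero(tc[i], tc[i + 1], v[i], v[i + 1])
      zc[[length(zc) + 1L]] <- data.frame(
        quantity = q, temperature_C = t0,
        direction = if (v[i] < 0) "neg_to_pos" else "pos_to_neg",
        low_confidence = lowconf(t0))
    }
    d <- diff(v)
    sd_ <- sign(d)
    nz <- which(sd_ != 0)
    if (length(nz) > 1) {
      for (k in seq_len(length(nz) - 1L)) {
        i <- nz[k]; j <- nz[k + 1L]
        if (sd_[i] != sd_[j]) {
          idx <- j  # grid point between the two opposite slopes
          ex[[length(ex) + 1L]] <- data.frame(
            quantity = q, temperature_C = tc[idx], value = v[idx],
            type = if (sd_[i] > 0) "max" else "min",
            low_confidence = lowconf(tc[idx]))
        }
      }
    }
  }
  TdS <- as_kelvin(tc) * profile$dS_J_molK / 1000
  comp <- if (stats::sd(profile$dH_kJ_mol) > 0 && stats::sd(TdS) > 0) {
    list(slope = unname(stats::coef(stats::lm(profile$dH_kJ_mol ~ TdS))[2]),
         correlation = stats::cor(profile$dH_kJ_mol, TdS))
  } else {
    list(slope = NA_real_, correlation = NA_real_)
  }
  structure(list(
    zero_crossings = if (length(zc)) do.call(rbind, zc) else
      data.frame(quantity = character(), temperature_C = numeric(),
                 direction = character(), low_confidence = logical()),
    extrema = if (length(ex)) do.call(rbind, ex) else
      data.frame(quantity = character(), temperature_C = numeric(),
                 value = numeric(), type = character(),
                 low_confidence = logical()),
    compensation = comp), class = "thermo_features")
}

#' @export
print.thermo_features <- function(x, ...) {
  cat("<thermo_features>\nzero crossings:\n")
  print.data.frame(x$zero_crossings)
  cat("extrema:\n")
  print.data.frame(x$extrema)
  cat(sprintf("enthalpy-entropy compensation: slope %.3f, r %.3f\n",
              x$compensation$slope, x$compensation$correlation))
  invisible(x)
}

#' Write a thermodynamic profile CSV
#'
#' @param profile A [thermo_profile()].
#' @param path File path.
#' @export
write_thermo_profile <- function(profile, path) {
  stopifnot(inherits(profile, "thermo_profile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Write a feature report as structured text
#'
#' @param features A `thermo_features` object.
#' @param path File path.
#' @export
write_feature_report <- function(features, path) {
  stopifnot(inherits(features, "thermo_features"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# zero crossings (quantity, temperature_C, direction, low_confidence)", con)
  z <- features$zero_crossings
  if (nrow(z)) writeLines(sprintf("%s %.3f %s %s", z$quantity, z$temperature_C,
                                  z$direction, z$low_confidence), con)
  writeLines("# extrema (quantity, temperature_C, value, type, low_confidence)", con)
  e <- features$extrema
  if (nrow(e)) writeLines(sprintf("%s %.3f %.6g %s %s", e$quantity,
                                  e$temperature_C, e$value, e$type,
                                  e$low_confidence), con)
  writeLines(sprintf("# compensation slope %.6g correlation %.6g",
                     features$compensation$slope,
                     features$compensation$correlation), con)
  invisible(path)
}
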