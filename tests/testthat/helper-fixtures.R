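# Shared builders for the test suite. Everything is generated in code;
# seeds are fixed per call site.

# A k_series-shaped data.frame from a true van't Hoff law, with optional
# i.i.d. Gaussian lnK noise.
make_k_series <- function(law, temp_C = seq(0, 90, by = 5),
                          sigma_lnK = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- eval_vh_law(law, temp_C)
  if (sigma_lnK > 0) y <- y + rnorm(length(y), sd = sigma_lnK)
  data.frame(temperature_C = temp_C, inv_T_K = 1 / (temp_C + 273.15),
             lnK = y, sigma_lnK = sigma_lnK)
}

# Random non-degenerate weight triples (percent, summing to 100).
random_weight_triples <- function(n, seed, min_phi = 1) {
  set.seed(seed)
  t(vapply(seq_len(n), function(i) {
    repeat {
      p <- runif(3)
      p <- 100 * p / sum(p)
      if (all(p >= min_phi)) return(p)
    }
  }, numeric(3)))
}

# Compact pseudo-random valid states for the algebraic-equivalence checks:
# concentrations in mol/L with all species populated.
random_states <- function(n, seed) {
  set.seed(seed)
  data.frame(
    Pt = runif(n, 30e-6, 300e-6),
    Lt = rep(20e-6, n),
    phi_F = NA, phi_I = NA, phi_S = NA
  ) -> d
  tr <- random_weight_triples(n, seed + 1)
  d$phi_F <- tr[, 1]; d$phi_I <- tr[, 2]; d$phi_S <- tr[, 3]
  d
}

# A small fast basis shared across spectra tests (fewer field points than
# the default axis, same window).
test_basis <- function(temperature = 25, n = 1024L) {
  default_basis(temperature, field = default_field_axis(n))
}

extdata <- function(...) {
  system.file("extdata", ..., package = "spinthermo", mustWork = TRUE)
}
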