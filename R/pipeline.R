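# End-to-end orchestration: simulate -> decompose -> analyze -> seqstats,
# driven by a YAML run configuration, with a reproducibility manifest
# written alongside every run. All randomness flows from one config seed;
# per-stage sub-seeds are derived deterministically from it.

#' Read a run configuration
#'
#' YAML with sections `experiment` (Pt_uM, Lt_uM, regime, T_min_C,
#' T_max_C, T_step_C), `truth` (per-transition van't Hoff laws `FI` and
#' `FS`, each dH_ref_kJ, dS_ref_J, dCp_kJ, T_ref_K), `spectra`
#' (sigma_phi_pp, spectrum_noise_rel, seed), `fitting` (families,
#' max_sign_changes), `output` (directory).
#'
#' @param path YAML file.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (sec in c("experiment", "truth", "spectra")) {
    if (is.null(cfg[[sec]])) stop(sprintf("config is missing section '%s'", sec))
  }
  cfg$.path <- normalizePath(path)
  class(cfg) <- "run_config"
  cfg
}

config_experiment <- function(cfg) {
  e <- cfg$experiment
  experiment_config(
    Pt = e$Pt_uM * 1e-6,
    Lt = (if (is.null(e$Lt_uM)) 20 else e$Lt_uM) * 1e-6,
    regime = if (is.null(e$regime)) "L" else e$regime,
    temperatures = seq(e$T_min_C, e$T_max_C, by = e$T_step_C))
}

config_law <- function(l) {
  vh_law(dH_ref = l$dH_ref_kJ * 1000, dS_ref = l$dS_ref_J,
         dCp = (if (is.null(l$dCp_kJ)) 0 else l$dCp_kJ) * 1000,
         T_ref = if (is.null(l$T_ref_K)) 310.15 else l$T_ref_K)
}

stage_seed <- function(seed, stage) {
  # deterministic per-stage sub-seed, kept within 32-bit integer range
  offsets <- c(simulate = 101L, noise = 211L, decompose = 307L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

write_manifest <- function(outdir, cfg, seed, inputs = character()) {
  man <- list(
    config = if (!is.null(cfg$.path)) unname(tools::md5sum(cfg$.path)) else NA,
    seed = seed,
    inputs = as.list(tools::md5sum(inputs)),
    package_version = as.character(utils::packageVersion("spinthermo")))
  jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Simulate a synthetic temperature series
#'
#' Generates the ground-truth weight series from the configured van't Hoff
#' laws, renders one composite spectrum per temperature (with optional
#' spectral noise), and writes: per-temperature spectrum files
#' (`spectrum_T<temp>.txt`), the noisy weight table (`weights.csv`), the
#' ground-truth weight table (`weights_truth.csv`), the generating lnK
#' table (`truth_lnK.csv`) and a manifest. Deterministic for a fixed seed.
#'
#' @param cfg A `run_config` (or path to one).
#' @param outdir Output directory (created if needed).
#' @param seed Overrides the config seed when non-NULL.
#' @return Invisibly, the noisy [weight_series()].
#' @export
run_simulate <- function(cfg, outdir, seed = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (!is.null(seed)) seed else cfg$spectra$seed
  if (is.null(seed)) stop("no seed in config or call")
  ec <- config_experiment(cfg)
  w <- generate_scenario(config_law(cfg$truth$FI), config_law(cfg$truth$FS),
                         ec,
                         sigma_phi = cfg$spectra$sigma_phi_pp,
                         seed = stage_seed(seed, "simulate"))
  noise_rel <- cfg$spectra$spectrum_noise_rel
  if (is.null(noise_rel)) noise_rel <- 0
  for (i in seq_len(nrow(w))) {
    tc <- w$temperature_C[i]
    basis <- default_basis(tc)
    sp <- render_mixture(basis, c(w$phi_F[i], w$phi_I[i], w$phi_S[i]))
    if (noise_rel > 0) {
      sp <- add_noise(sp, noise_rel, seed = stage_seed(seed, "noise") + i)
    }
    write_spectrum(sp, file.path(outdir, sprintf("spectrum_T%05.1f.txt", tc)))
  }
  write_weight_series(w, file.path(outdir, "weights.csv"))
  write_weight_series(attr(w, "truth"), file.path(outdir, "weights_truth.csv"))
  utils::write.csv(attr(w, "truth_lnK"), file.path(outdir, "truth_lnK.csv"),
                   row.names = FALSE)
  write_manifest(outdir, cfg, seed)
  invisible(w)
}

#' Decompose a directory of spectra into a weight table
#'
#' Reads every `spectrum_*.txt` in `spectra_dir`, decomposes each against
#' the default component basis at its recorded temperature, and writes one
#' CSV row per temperature (sorted ascending) with the NNLS weights and
#' the residual RMSD (percentage of peak-to-peak amplitude) as
#' `sigma_phi`. Unreadable files are skipped with a warning.
#'
#' @param spectra_dir Directory of two-column ASCII spectra.
#' @param out_csv Output weight CSV.
#' @return Invisibly, the [weight_series()].
#' @export
run_decompose <- function(spectra_dir, out_csv) {
  files <- list.files(spectra_dir, pattern = "^spectrum_.*\\.txt$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no spectrum files in ", spectra_dir)
  rows <- list()
  for (f in files) {
    res <- tryCatch({
      sp <- read_spectrum(f)
      basis <- default_basis(sp$temperature)
      d <- decompose_spectrum(sp, basis)
      data.frame(temperature_C = sp$temperature,
                 phi_F = d$weights[["F"]], phi_I = d$weights[["I"]],
                 phi_S = d$weights[["S"]], sigma_phi = d$rmsd)
    }, error = function(e) {
      warning(sprintf("skipping %s: %s", basename(f), conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L) stop("no readable spectra")
  d <- do.call(rbind, rows)
  d <- d[order(d$temperature_C), ]
  w <- weight_series(d$temperature_C, d$phi_F, d$phi_I, d$phi_S, d$sigma_phi)
  write_weight_series(w, out_csv)
  invisible(w)
}

#' Analyze a weight table into thermodynamic profiles
#'
#' For each of the four transitions (or a subset): computes the binding
#' constants with per-point exclusion, selects a van't Hoff model, fits
#' error bands when weight errors are available, and writes the K table,
#' fit report, thermodynamic profile and feature report. Transitions with
#' fewer than 5 retained points are skipped with a warning.
#'
#' @param weights A [weight_series()] or path to a weight CSV.
#' @param cfg An [experiment_config()] (Pt, Lt of the experiment).
#' @param outdir Output directory.
#' @param transitions Character subset of c("F-T", "F-I", "F-S", "I-S").
#' @param families Candidate [model_family()] list.
#' @param max_sign_changes Oscillation-screen threshold for
#'   [select_model()].
#' @return Invisibly, a named list of [thermo_profile()]s.
#' @export
run_analyze <- function(weights, cfg, outdir,
                        transitions = c("F-T", "F-I", "F-S", "I-S"),
                        families = default_families(),
                        max_sign_changes = 4L) {
  if (is.character(weights)) weights <- read_weight_series(weights)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  profiles <- list()
  for (tr in transitions) {
    ks <- switch(tr,
                 "F-T" = k_total(weights, cfg),
                 "I-S" = k_interconversion(weights, cfg),
                 k_coupled(weights, cfg, tr))
    ex <- attr(ks, "excluded_points")
    if (nrow(ex) > 0) {
      message(sprintf("%s: %d point(s) excluded (%s)", tr, nrow(ex),
                      paste(unique(ex$reason), collapse = "; ")))
    }
    if (nrow(ks) < 5L) {
      warning(sprintf("transition %s skipped: only %d retained points",
                      tr, nrow(ks)))
      next
    }
    fit <- select_model(ks, families, max_sign_changes)
    if (any(ks$sigma_lnK > 0)) fit <- fit_error_bands(ks, fit)
    tag <- gsub("-", "", tr)
    write_k_series(ks, file.path(outdir, sprintf("K_%s.csv", tag)))
    write_fit_report(fit, file.path(outdir, sprintf("fit_%s.txt", tag)))
    prof <- thermo_profile(fit, transition = tr)
    write_thermo_profile(prof, file.path(outdir, sprintf("thermo_%s.csv", tag)))
    write_feature_report(extract_features(prof),
                         file.path(outdir, sprintf("features_%s.txt", tag)))
    profiles[[tr]] <- prof
  }
  invisible(profiles)
}

#' Sequence statistics report
#'
#' Whole-sequence GRAVY and net charge for every FASTA sequence; optional
#' per-domain GRAVY/charge when a domain CSV is given (domains refer to
#' the first sequence unless `domain_seq` names another); optional
#' pairwise identity matrix when an alignment is given.
#'
#' @param fasta Path to a FASTA file (one or more sequences).
#' @param alignment Optional alignment path (aligned FASTA or Clustal).
#' @param domains Optional domain CSV path (name,start,end).
#' @param out Optional output report path (plain text).
#' @param alignment_format "fasta" or "clustal".
#' @param domain_seq Name of the sequence the domains refer to.
#' @return List with `per_sequence` (data.frame id, length, gravy,
#'   net_charge), `per_domain` (data.frame or NULL), `identity` (matrix or
#'   NULL).
#' @export
run_seqstats <- function(fasta, alignment = NULL, domains = NULL,
                         out = NULL, alignment_format = "fasta",
                         domain_seq = NULL) {
  seqs <- read_fasta(fasta)
  per_seq <- data.frame(
    id = names(seqs),
    length = nchar(seqs),
    gravy = round(vapply(seqs, gravy, numeric(1)), 3),
    net_charge = vapply(seqs, net_charge, numeric(1)),
    row.names = NULL)
  per_dom <- NULL
  if (!is.null(domains)) {
    dom <- read_domains(domains)
    target <- if (is.null(domain_seq)) names(seqs)[1] else domain_seq
    s <- seqs[[target]]
    per_dom <- data.frame(
      sequence = target, name = dom$name, start = dom$start, end = dom$end,
      gravy = round(mapply(function(a, b) domain_gravy(s, a, b),
                           dom$start, dom$end), 3),
      net_charge = mapply(function(a, b) net_charge(s, positions = a:b),
                          dom$start, dom$end))
  }
  idm <- NULL
  if (!is.null(alignment)) {
    aln <- read_alignment(alignment, alignment_format)
    idm <- identity_matrix(aln)
  }
  if (!is.null(out)) {
    con <- file(out, "w")
    on.exit(close(con))
    writeLines("# per-sequence GRAVY and net charge", con)
    utils::write.csv(per_seq, con, row.names = FALSE)
    if (!is.null(per_dom)) {
      writeLines("# per-domain GRAVY and net charge", con)
      utils::write.csv(per_dom, con, row.names = FALSE)
    }
    if (!is.null(idm)) {
      writeLines("# pairwise identity (%), rounded", con)
      utils::write.csv(round(idm), con, row.names = TRUE)
    }
  }
  list(per_sequence = per_seq, per_domain = per_dom, identity = idm)
}
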