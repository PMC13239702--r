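# spinthermo

Temperature-dependent binding thermodynamics of a spin-labeled ligand and
a transport protein, computed from continuous-wave EPR spectral component
weights.

## The problem

CW EPR spectra of a nitroxide-labeled fatty acid in the presence of a
fatty-acid binding protein (FABP) superimpose three sub-spectra: free
ligand (F), ligand loosely attached to the protein surface (I), and
ligand strongly bound in the pocket (S). Decomposing each spectrum of a
temperature series yields weights Φ_F/Φ_I/Φ_S (%), which map to
concentrations via [X] = (Φ_X/100)·L_t at fixed total ligand
concentration L_t. From these, four association equilibria are
quantified (T = I + S is the total bound fraction):

    K_F-T = [T] / ([F](P_t − [T]))
    K_F-I = [I] / ([F](P_t − [I] − [S]))      (1:1 coupled model)
    K_F-S = [S] / ([F](P_t − [I] − [S]))
    K_I-S = Φ_S / Φ_I

ln K against 1/T is fitted with weighted model families (polynomials,
Boltzmann sigmoid, exponential, plus classic linear and
constant-ΔCp van't Hoff forms), the best family is selected by reduced
χ² with an oscillation-artifact screen, and the full thermodynamic
profile follows:

    ΔG° = −RT ln K        ΔH° = −R d(ln K)/d(1/T)
    ΔS° = (ΔH° − ΔG°)/T   ΔCp° = dΔH°/dT

with error bands refit to ln K ± σ and features (zero crossings, extrema,
enthalpy–entropy compensation statistics) extracted from the curves. A
synthetic-data generator (exact coupled-equilibrium solver + parametric
nitroxide lineshapes + NNLS decomposition) closes the loop for
validation, and sequence utilities (Kyte–Doolittle GRAVY, net charge,
percent identity) support isoform comparison. The package is aimed at
spectroscopists extracting interaction thermodynamics from
multi-component spectral series.

## Worked example

Simulate an L-regime experiment (50 µM protein, 20 µM ligand, 0–90 °C in
5 K steps) from known constant-ΔCp truths, then analyze the
free-to-intermediate transition:

```r
library(spinthermo)

cfg <- experiment_config(Pt = 50e-6, regime = "L",
                         temperatures = seq(0, 90, 5))
w <- generate_scenario(vh_law(-25e3, -35, dCp = -1.2e3),   # F-I truth
                       vh_law(-35e3, -60, dCp = -1.5e3),   # F-S truth
                       cfg, sigma_phi = 1.0, seed = 42)
head(as.data.frame(w), 3)
#>   temperature_C    phi_F     phi_I    phi_S sigma_phi
#> 1             0 95.32253 0.6665651 4.010904         1
#> 2             5 94.17860 1.7854257 4.035976         1
#> 3            10 92.37257 1.3634027 6.264030         1

ks  <- k_coupled(w, cfg, "F-I")        # lnK vs 1/T with propagated errors
fit <- fit_error_bands(ks, select_model(ks))
fit$family$kind
#> [1] "poly2"

prof <- thermo_profile(fit, transition = "F-I")
round(prof[prof$temperature_C == 37, 1:5], 3)
#>    temperature_C dG_kJ_mol dH_kJ_mol dS_J_molK dCp_kJ_molK
#> 75            37   -15.438    -6.146     29.96      -0.219

extract_features(prof)$zero_crossings
#>    quantity temperature_C  direction low_confidence
#> 1 dH_kJ_mol      11.26332 pos_to_neg          FALSE
```

Reading: at 37 °C intermediate binding is exergonic (ΔG° ≈ −15.4 kJ/mol)
and entropy-driven (TΔS° ≈ +9.3 kJ/mol against ΔH° ≈ −6.1 kJ/mol), the
fitted curve turns from endo- to exothermic at ~11 °C, and the negative
ΔCp° points to burial of non-polar surface. Per-point exclusions (e.g.
temperatures where a species concentration is zero) are logged, never
fatal.

File-based workflows use `run_simulate()`, `run_decompose()`,
`run_analyze()` and `run_seqstats()` (CSV/ASCII/FASTA in and out); a thin
command-line wrapper ships in `inst/cli/spinthermo.R`. Sequence metrics:

```r
seqs <- read_fasta(system.file("extdata", "fabp_all.fasta",
                               package = "spinthermo"))
round(vapply(seqs, gravy, numeric(1)), 3)
#> sp|P05413|FABP3_HUMAN sp|P15090|FABP4_HUMAN sp|Q01469|FABP5_HUMAN
#>                -0.265                -0.249                -0.458
```

See `vignettes/binding-thermodynamics.Rmd` for the model assumptions,
parameter choices, error model and known limitations.

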