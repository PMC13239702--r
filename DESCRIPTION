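Package: spinthermo
Title: Binding Thermodynamics from Spin-Probe EPR Spectral Weights
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives full temperature-dependent thermodynamic profiles
    (Gibbs energy, enthalpy, entropy and heat capacity changes) for the
    coupled binding equilibria of a spin-labeled ligand and a transport
    protein from continuous-wave EPR spectral component weights. Includes a
    parametric nitroxide triplet generator and non-negative least-squares
    spectral decomposition, the 1:1 coupled-equilibrium mass-action model
    for the free, intermediately bound and strongly bound ligand states,
    weighted van't Hoff model fitting with chi-squared model selection and
    refit-based error bands, Gaussian propagation of spectral-weight errors,
    transition-feature extraction, and Kyte-Doolittle hydropathy, net-charge
    and percent-identity sequence comparison utilities.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    pracma,
    minpack.lm,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
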