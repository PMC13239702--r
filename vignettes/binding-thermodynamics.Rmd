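---
title: "From spectral weights to binding thermodynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From spectral weights to binding thermodynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinthermo)
```

## The physical picture

A nitroxide-labeled fatty acid in solution with a lipid-transport protein
(a FABP-class beta barrel) populates three dynamic states that CW EPR can
distinguish by rotational mobility: free probe (F, fast tumbling, narrow
triplet), probe loosely attached to the protein surface or portal region
(I, intermediate mobility), and probe folded into the binding pocket (S,
strongly immobilized, powder-like wide pattern). The composite spectrum is
a weighted superposition of the three sub-spectra, and the weights
$\Phi_F, \Phi_I, \Phi_S$ (percent, summing to 100) measured across a
temperature series are the raw material for everything this package
computes.

Because the spectra are normalized to a constant total ligand
concentration $L_t$, each weight converts directly to a concentration,
$[X] = (\Phi_X / 100)\, L_t$. With total bound ligand $[T] = [I] + [S]$,
four association transitions are defined:

* **F-T** (total binding): $K = \dfrac{[T]}{[F](P_t - [T])}$
* **F-I** and **F-S** (coupled individual binding):
  $K_{F\text{-}I} = \dfrac{[I]}{[F](P_t - [I] - [S])}$, and the same with
  $[S]$ in the numerator for F-S
* **I-S** (interconversion): $K = \Phi_S / \Phi_I$, dimensionless

The coupled forms assume 1:1 stoichiometry and that intermediately and
strongly bound ligands sit mostly on different protein molecules, so both
transitions compete for the same free-protein pool
$P_t - [I] - [S]$. When the co-appearing state is unpopulated, the coupled
form reduces exactly to the total-binding expression. The test suite
verifies the algebraic equivalence of these compact mass-action forms
with their fully expanded counterparts on a thousand random states, plus
the shared-denominator identity
$K_{I\text{-}S} = K_{F\text{-}S}/K_{F\text{-}I}$.

Bimolecular constants are multiplied by a standard concentration
$c^\circ = 1\,$M before taking logarithms, so $\ln K$ is dimensionless and
$\Delta G^\circ$ is a true standard quantity; this shifts every $\ln K$
curve by a constant and therefore leaves enthalpies, heat capacities and
all transition temperatures untouched. The interconversion constant is
already dimensionless.

### Degenerate points

Whenever a required species is absent at a temperature ($[F] = 0$,
$\Phi_I = 0$, or $\Phi_S = 0$ for the relevant transition, with a
numerical floor of $10^{-10}$ mol/L on denominators), that point is
excluded with a recorded reason rather than aborting the analysis. This
mirrors how real systems restrict each transition to the temperature
range where its species are populated; a transition with fewer than five
retained points is skipped entirely.

## Error model

Spectral simulation/decomposition errors are carried as one absolute
percentage-point error per temperature (the residual RMSD in percent of
the peak-to-peak amplitude), applied equally and independently to all
three weights. They are propagated into $\sigma_{\ln K}$ by first-order
Gaussian propagation with a central-difference Jacobian (step 0.01 pp).
For the interconversion this reproduces the analytic result
$\sigma^2_{\ln K} = (\sigma/\Phi_S)^2 + (\sigma/\Phi_I)^2$ to $10^{-6}$,
which the tests check.

## Van't Hoff fitting

The fit variable is $x = 1/T$ throughout, with weights
$1/\sigma_{\ln K}^2$ (unit weights when no errors are supplied). Two
kinds of model are available:

* **Physical forms**: the linear van't Hoff line
  $\ln K = -(\Delta H^\circ/R)x + \Delta S^\circ/R$, and the
  constant-$\Delta C_p$ form built from
  $\Delta H(T) = \Delta H_{ref} + \Delta C_p (T - T_{ref})$ and
  $\Delta S(T) = \Delta S_{ref} + \Delta C_p \ln(T/T_{ref})$. Both are
  linear in their parameters, so the fits are exact weighted least
  squares; freezing $\Delta C_p = 0$ reproduces the linear fit to
  machine precision (a nesting the tests assert).
* **Parametrized families** for curves the physical forms cannot follow:
  polynomials of order 2-6 in $x$, the Boltzmann sigmoid
  $y = A_2 + (A_1 - A_2)/(1 + e^{(x - x_0)/dx})$, and the exponential
  $y = y_0 + A e^{R_0 x}$. These carry no physical meaning; they exist to
  describe the $\ln K(x)$ curve well enough to differentiate it.

All nonlinear fits use fixed, closed-form, data-derived starting values
(Boltzmann plateaus from the terminal points, midpoint crossing for
$x_0$, span/10 for $dx$; exponential rate from the log-ratio of terminal
differences), so every fit is deterministic and reproducible.

### Model selection

Candidates (default: poly2-poly4, Boltzmann, exponential; poly5/6 are
opt-in because over-parametrization manufactures spurious extrema) are
compared by weighted reduced $\chi^2$ after two screens: non-converged
fits are dropped, and fits whose first derivative changes sign more than
4 times inside the data range are rejected as oscillation artifacts
regardless of their $\chi^2$.

The tie-break toward fewer parameters uses an adaptive window: two fits
are considered tied when their reduced $\chi^2$ differ by less than one
relative standard deviation of a reduced $\chi^2$ at the best fit's
degrees of freedom, $\sqrt{2/\mathrm{dof}}$ (floored at 1%). The
motivation is that reduced-$\chi^2$ differences between nested
polynomial orders on noise-dominated data fluctuate on exactly this
scale, so a much narrower window turns selection into a coin flip among
statistically indistinguishable fits instead of resolving to the
simplest one. With this window, noisy linear data selects poly2 in
roughly 90% of runs while genuinely sigmoidal data still selects the
Boltzmann family essentially always; both behaviors are exercised in the
tests. A fixed numeric window can be supplied instead via `tie`.

### Error bands

Bands are built by refitting the selected family to the shifted point
sets $\ln K \pm \sigma_{\ln K}$, not from the parameter covariance. This
matches how systematic simulation errors behave: the plausible extreme
curves are themselves smooth members of the family. For linear-in-
parameter families with homoscedastic errors this provably shifts the
central curve by $\pm\sigma$; with heteroscedastic errors the two band
curves can in principle cross the centre locally, which is why profile
bands are reported as the per-point envelope (min/max) of the two band
curves.

## Thermodynamic profiles

On a uniform temperature grid (default 0-90 °C in 0.5 K steps, clipped to
each transition's fitted $1/T$ domain):

$$\Delta G^\circ = -RT \ln K, \qquad
  \Delta H^\circ = -R \frac{d\ln K}{d(1/T)}, \qquad
  \Delta S^\circ = \frac{\Delta H^\circ - \Delta G^\circ}{T}, \qquad
  \Delta C_p^\circ = \frac{d \Delta H^\circ}{dT}$$

Derivatives are analytic for every built-in family (the second derivative
gives $\Delta C_p = R\,\ln K''(x)/T^2$); the tests confirm agreement with
central differences to $10^{-6}$ relative. Because $\Delta S$ is defined
through the other two quantities, the Gibbs-Helmholtz identity
$\Delta G = \Delta H - T\Delta S$ holds on every profile by construction,
and the suite asserts it at machine precision on every emitted profile.

Feature extraction reports zero crossings (sign change plus linear
interpolation between bracketing grid points) and extrema (discrete
first-derivative sign changes) of all four quantities. Features within
two grid steps of a domain end are flagged low-confidence: fitted curves
are least constrained at the data borders, where spurious enthalpy and
entropy extrema are a known failure mode of this kind of analysis.
Enthalpy-entropy compensation is summarized descriptively as the slope
and correlation of $\Delta H$ against $T\Delta S$ over the grid; no
mechanistic claim is attached.

## The synthetic-data generator

No public per-temperature weight tables exist for the systems that
motivated this package, so validation rests on a generator that emulates
the study design:

* **Experiment geometry**: ligand $L_t = 20\,\mu$M; protein regimes
  L/M/H at $P_t = 50/100/200\,\mu$M; temperature grids inside 0-90 °C
  (typically 19 points at 5 K steps).
* **Truth laws**: each individual transition gets a constant-$\Delta C_p$
  van't Hoff law; typical magnitudes used in tests
  ($\Delta H_{ref} \approx -20$ to $-35$ kJ/mol,
  $\Delta C_p \approx -1.5$ kJ/(mol K), $T_{ref} = 310.15$ K) sit in the
  range reported for fatty-acid/FABP binding. The coupled equilibrium is
  then solved exactly per temperature: with
  $\kappa = K_{F\text{-}I} + K_{F\text{-}S}$, the free-ligand
  concentration is the positive root of
  $\kappa f^2 + f(1 + \kappa(P_t - L_t)) - L_t = 0$, and the solver
  round-trips through the mass-action expressions to $10^{-9}$ relative
  (tested to $10^{-14}$).
* **Weight noise**: Gaussian with a per-temperature SD in percentage
  points (the published error convention reports spectral RMSDs of a few
  percent as absolute weight errors), truncated at zero and renormalized
  to 100 so downstream invariants hold exactly.
* **Spectra**: each component is a triplet of first-derivative
  pseudo-Voigt lines at $B_0 - a_{iso} m_I$ with peak-to-peak widths
  $\Delta B(m_I) = A + B m_I + C m_I^2$, normalized to unit double
  integral (cumulative trapezoid twice) on a 332.5-342.5 mT, 4096-point
  axis. The strongly bound state is represented by a large effective
  splitting (~3.2 mT) with broad lines; $a_{iso}$ decreases and
  $\tau_c$ shortens with temperature (linear and log-linear anchor
  interpolation respectively). This parametric lineshape is deliberately
  not a slow-motional (stochastic-Liouville) simulation: only the weight
  fractions feed the thermodynamic pipeline, so the basis functions need
  to be realistic in overlap and relative amplitude, not
  spectroscopically exact. Consequences of the simplification: no
  modulation or saturation artifacts, no g-anisotropy, and a cleaner
  separation between components than slow-motional reality; passing
  round-trip tests therefore demonstrates correctness of the
  decomposition and thermodynamics machinery, not of any lineshape
  theory.

Decomposition is non-negative least squares on the three basis spectra
with weights renormalized to 100; a basis condition number above $10^8$
flags the result ill-conditioned. Noiseless round trips recover weights
to $10^{-13}$ pp; at 1% (of peak-to-peak) spectral noise the mean
recovery error is about 1 pp, dominated by the low-amplitude strongly
immobilized component — the same reason real analyses carry
percentage-point RMSD errors on their weights.

## Sequence comparison

GRAVY is the mean Kyte-Doolittle hydropathy (the original 20-value,
one-decimal scale), whole-sequence or over residue subsets; net charge
counts K/R against D/E with histidine neutral (a neutral-pH
approximation). Percent identity of aligned pairs supports two
denominator conventions, because published values routinely differ by
1-2 points between them: columns with at least one residue (gaps count
as mismatches; the default) or aligned-residue columns only. The bundled
FABP3/4/5 sequences reproduce published whole-sequence GRAVY values
(-0.265 / -0.249 / -0.458) exactly, and the bundled triple alignment
gives pairwise identities of 65 / 55 / 50 percent (the last differing by
one point from the commonly cited 51%, inside the convention ambiguity).

## Problem sizes and numerical choices

The test and validation workloads use 19-temperature grids, 1000-state
algebraic checks, 100-200-draw Monte Carlo loops and 1024-4096-point
field axes; these sizes make every property checkable in seconds while
matching the data volumes the method is designed for. Other fixed
choices: $R = 8.314$ J/(mol K); $T(K) = T(°C) + 273.15$; denominator
floor $10^{-10}$ mol/L; central-difference step 0.01 pp for the error
Jacobian; weight triples renormalized to exactly 100 before any
mass-action arithmetic.

## Known limitations

* Only the 1:1 coupled binding model is implemented; cooperative or
  n:1 stoichiometries and competition with unlabeled ligands are out of
  scope.
* The parametrized fit families are descriptive; enthalpies and heat
  capacities inherit their artifacts, which is precisely why the
  oscillation screen, the border flags, and the classic van't Hoff
  cross-checks exist.
* Band construction assumes the refit-family philosophy; it does not
  produce statistically calibrated confidence intervals.
* The spectral generator is parametric, not slow-motional; conclusions
  about real spectra require real simulations upstream.
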