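---
title: "Models and methods: proton-coupled conformational exchange by R1rho and CEST"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: proton-coupled conformational exchange by R1rho and CEST}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protex)
```

# The problem

Chemical-exchange NMR can detect conformational states of an RNA that are
populated below 1% and live for milliseconds, through the exchange
contribution they add to rotating-frame relaxation (R1ρ) and through the
secondary dip they produce in saturation-transfer (CEST) profiles. When such
an excited state (ES) is stabilized by protonation of a nucleobase, its
population becomes pH dependent. Two coupled quantities then matter and are
easy to conflate:

* the **intrinsic pKa** of the protonation site in the excited conformation,
  which reflects local proton affinity (hydrogen bonding in a wobble C⁺–C
  mismatch raises it well above that of an unpaired cytosine), and
* the **apparent pKa** of the overall ground-state ⇌ protonated-excited-state
  transition, which folds in the free-energy cost of the conformational
  change:
  $$\mathrm{p}K_a^{app} = \mathrm{p}K_a^{intr} + \log_{10} K_{conf},$$
  with $K_{conf} = [\mathrm{ES}]/[\mathrm{GS}]$ the conformational equilibrium
  constant between the *neutral* species.

For $K_{conf} \sim 10^{-3}$ the apparent pKa sits three units below the
intrinsic one, which is why a state with an intrinsic pKa above 7 can show
almost no pH dependence until the solution is pushed to pH ≈ 5 and below.
`protex` implements the forward models, fits, thermodynamics and kinetics
needed to work quantitatively in this regime.

# Forward models

## Bloch–McConnell evolution

Both experiments are modeled by the coupled magnetization evolution
equations. For $N$ exchanging states the magnetization is the
$3N$-vector $(M_x, M_y, M_z)$ per state; the generator combines, per state,
the rotating-frame precession at offset $\delta_i$, the nutation by the
applied field $\omega_1$ (along $x$), transverse and longitudinal relaxation
$R_2$ and $R_1$ (one pair shared by all states, the standard assumption for
sparsely populated states), and first-order exchange couplings $k_{ij}$
satisfying detailed balance $p_i k_{ij} = p_j k_{ji}$. Offsets are referenced
to the population-average resonance and converted from ppm via
$2\pi \cdot \mathrm{ppm} \cdot \nu_{larmor}$ (MHz). The homogeneous form
(no recovery term) is used throughout: both observables are decays toward
zero under the experiment's normalization conventions.

Propagation is by complex eigendecomposition of the evolution matrix, with a
scaling-and-squaring matrix exponential as fallback when the eigenvector
matrix is ill-conditioned (reciprocal condition below $10^{-13}$). The
compiled core (RcppArmadillo) makes the Monte Carlo resampling loops
practical on one CPU.

## The R1ρ estimator

`simulate_r1rho()` mirrors the experiment rather than reading off an
eigenvalue: magnetization is tilted along the effective field, evolved to
five evenly spaced delays chosen at run time to reach roughly 70% decay
(capped at 120 ms), projected onto the initial effective-field axis, and the
projections are fitted with a mono-exponential. Synthetic and measured data
therefore pass through an identical estimator.

The initial alignment follows the exchange regime, switching at
$k_{ex}/|\Delta\omega| = 5$: at or above the threshold the population-average
magnetization is tilted along the average effective field; below it, along
the ground-state effective field. The threshold is a documented default, not
a literal prescription from any one instrument's processing pipeline. A
dedicated property test shows the two conventions agree to better than 1% of
$R_{ex}$ at and beyond the regime boundaries for minor-state populations up
to ~2% — the regime of the systems this package targets. The agreement
degrades for populations above ~5%, where the choice of convention is a real
modeling decision.

One practical consequence of the five-delay estimator: in the no-exchange
limit with $R_1 \neq R_2$ the fitted rate matches the closed form
$R_1\cos^2\theta + R_2\sin^2\theta$ only to order
$((R_2-R_1)/\omega_{eff})^2$ — about $10^{-6}$–$10^{-4}$ relative at
realistic powers — because the initial condition is not exactly the slowest
eigenvector. With $R_1 = R_2$ the projection decay is exact. Tests assert
both statements at their own accuracy.

## CEST

`simulate_cest()` evolves z-magnetization under saturation for the relaxation
delay (default 100 ms), averages over B1 inhomogeneity with a 5-point
Gauss–Hermite quadrature over a Gaussian of relative SD 0.10 (a configurable
default standing in for the per-instrument calibration), and normalizes by
the zero-delay reference (the dominant-state equilibrium magnetization). The
secondary dip localizes the minor state's shift offset; its depth grows with
the minor population.

# Fitting

All least-squares problems are solved with trust-region Levenberg–Marquardt
(`minpack.lm::nls.lm`) on transformed parameters: populations through a
logit (bounded to (0, 0.5) for CEST, where the "minor" label is otherwise
unidentified), rates and relaxation rates through a log. Weights are
$1/\sigma^2$; points without reported uncertainties get unit weight with a
warning. Multi-start grids guard against local minima — eight starts
log-spaced in $k_{ex} \in [50, 5\times10^4]$ s⁻¹ and
$p \in [10^{-4}, 0.3]$ for the global two-state fit, pKa × log-K_conf grids
for the thermodynamic fit — and ties are broken by the lowest χ², then the
lowest start index, so fits are deterministic for a fixed seed and start
list. Input rows are put into a canonical order before fitting, which makes
the result exactly invariant to row permutations.

Parameter uncertainties use parametric Monte Carlo resampling (500 iterations
by default): each datum is redrawn from a normal centered on the best-fit
prediction with the reported SD, the model is refit from the best-fit
parameters, and the SD over iterations is reported. A residual bootstrap was
considered and rejected as the default because the generator's noise model is
exactly the parametric one. CEST fits additionally report standard errors
from the covariance diagonal, as is conventional for that experiment.

## The constrained three-state fit

For a linear topology GS ⇌ GS⁺ ⇌ ES2⁺ the protonation step is pinned:
$k_{ex,prot} = k_{prot}([\mathrm{H}^+] + 10^{-\mathrm{p}K_{a,GS}})$ with the
diffusion-limited $k_{prot} = 6\times10^{11}$ M⁻¹s⁻¹ and the ground-state
site pKa of 4.0 as defaults, and the protonated ground-state fraction
$f_{GS^+} = 10^{\mathrm{p}K_{a,GS}-\mathrm{pH}}/(1+10^{\mathrm{p}K_{a,GS}-\mathrm{pH}})$.
Per-pH apparent minor-state populations are supplied externally (in practice
from the per-pH two-state fits). Free parameters are the shared
conformational exchange rate $k_{ex,conf}$ and, per probe, the two shift
offsets (GS→GS⁺ starting at 0, GS→ES2⁺ starting at the two-state value) and
the relaxation pair; relaxation rates are shared across pH within a probe, a
simplification appropriate for the synthetic suites where fields do not
change across pH. When conformational change is rate-limiting the fit is
insensitive to the pinned protonation rate — the package's sensitivity test
perturbs $k_{prot}$ ten-fold and requires the χ² to move by less than 10%.

## Model selection for CEST

Profiles are fitted with and without exchange
($p_{ES} = k_{ex} = \Delta\omega = 0$) and compared on the weighted-χ²
scale with $\mathrm{AIC} = \chi^2 + 2k$ and
$\mathrm{BIC} = \chi^2 + k\ln n$; Akaike weights
$w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$ sum to one. One statistical
point deserves emphasis: under the no-exchange truth the exchange model can
always chase the deepest noise excursion somewhere in the offset window (the
shift offset is a scanned nuisance parameter), so its spurious χ² gain
behaves like a scan statistic — asymptotically at least $\chi^2_3$. The AIC
weight of the true null therefore exceeds 0.7 in at most ~77% of repeats no
matter the noise level, while the *ranking* (argmax of wAIC) and the BIC
weight, whose penalty grows with the number of points, are reliable. The
test suite asserts exactly those calibrated statements.

# The five-state thermodynamic model

With two excited states, each with a neutral and a protonated form, the
Boltzmann weights relative to the neutral ground state are
$K_{conf}^{ES}$ (neutral) and $K_{conf}^{ES}\, 10^{\mathrm{p}K_a^{ES}-\mathrm{pH}}$
(protonated), assuming a Hill coefficient of 1 and
$[\mathrm{H}^+] = 10^{-\mathrm{pH}}$ exactly. The apparent ES2 population —
what exchange probes that cannot resolve protonation actually measure — is
the ES2 + ES2⁺ share of the five-state sum. Useful consequences, all covered
by tests:

* the pH at which $[\mathrm{ES2}^+] = [\mathrm{GS}]$ is exactly the apparent
  pKa;
* the free-energy penalty $\Delta G = -RT\ln(p_{ES2}+p_{ES2^+})$
  ($R = 1.987204\times10^{-3}$ kcal mol⁻¹ K⁻¹, $T = 298.15$ K) plateaus at
  $-RT\ln K_{conf}^{ES2} \approx 4.15$ kcal/mol at high pH for
  $K_{conf}^{ES2} = 0.9\times10^{-3}$;
* with a competing protonated ES1 present, both protonated weights scale as
  $10^{-\mathrm{pH}}$, so at low pH the penalty saturates at a finite floor
  (~2.0 kcal/mol for the default parameter set) instead of vanishing — the
  competing state caps how cheap the minor state can ever become. The curve
  is monotone in pH; the floor, not an interior minimum, is the robust
  feature.

The pH-series fit profiles out measurement noise by weighted least squares
with the multi-start grid above. The degeneracy scan refits $K_{conf}$ at
each grid pKa and reports the $\Delta\chi^2 = 1$ band — a 1σ (≈68%)
interval for one profiled parameter. Because a higher intrinsic pKa can be
compensated by a lower $K_{conf}$ whenever the measured pH range sits far
below the intrinsic pKa, the band's upper edge is frequently open; the
scientifically meaningful output is the lower bound.

# Kinetics and mechanism

The explicit three-state simulator builds the rate matrix for
ES1⁺ ⇌ GS ⇌ ES2⁺ (off-diagonals $k_{on}[\mathrm{H}^+]$ and $k_{off}$;
columns sum to zero) and solves $\dot P = KP$ by eigendecomposition, with a
fixed-step RK4 fallback if the eigenvector matrix is defective. The
automatic time window extends until the residual slope falls below
$10^{-6}$ s⁻¹, which for slow branches means milliseconds — equilibrium,
not a fixed window, is the stopping criterion. Apparent two-state
observables come from a mono-exponential fit of the ES2⁺ channel's approach
to equilibrium; a runs test on the residuals flags visibly bi-exponential
traces, ignoring numerically negligible misfits.

Mechanism discrimination uses the pH dependence of the forward and reverse
rates. `fit_proton_linear()` fits $k_{forward} = k_{on}[\mathrm{H}^+]$
through the origin and $k_{reverse} = k_{off}$ as a weighted mean, and also
reports the slope of a free-intercept companion fit: a through-origin slope
is necessarily positive even for pH-flat data, so the *zero-slope* signature
of conformational selection with rate-limiting conformational change is
tested on the free slope. The four limiting mechanisms and their predicted
rates, kinetic solvent isotope effects (a 2–4× heavier-water slowdown of
diffusion-limited protonation and a +0.1 pKa shift), and mutant fold-change
predictions follow the standard induced-fit / conformational-selection
taxonomy and are pure arithmetic on the microscopic constants.

# Synthetic data and what the tests show

Generators are pure functions of (truth, scheme, noise, seed): identical
inputs give bit-identical tables, zero noise returns the forward model
exactly, and the SD columns carry the noise model's sigma so refits have
reduced χ² near 1. Default conditions mirror the regime of interest: minor
populations 0.1–15%, exchange rates 300–30 000 s⁻¹, shift offsets up to
5 ppm at 600–900 MHz fields, 2% relative noise on R1ρ rates and 0.01
absolute on normalized CEST intensities (0.005 in the model-selection
suites, typical of good-S/N imino-proton profiles).

Problem sizes in the test suite are chosen to keep the whole suite near
fifteen minutes on one CPU while preserving each experiment's logic:
spin-lock grids of three to four powers (100–3000 Hz) × 6–8 offsets per
probe — several powers are what decouple the population from the exchange
rate — eight repeats of the 500-iteration Monte Carlo coverage experiment,
60 random models for the ODE-oracle equivalence, 20 simulations per truth
for model selection, and a three-probe five-pH pipeline for the kinetics
round trip.

What passing does and does not show: the suites demonstrate correctness of
the propagators (against independent dense ODE integration in plain R via
deSolve), internal consistency of the estimator pipeline, calibration of the
Monte Carlo uncertainties under the parametric noise model, and
recoverability of the generating parameters under realistic grids and noise.
They do not probe pulse-sequence imperfections, Hartmann–Hahn transfer,
baseline or phase artifacts, field-dependent relaxation, or noise that is
correlated across offsets — real-data effects outside the generator's scope.

# Numerical choices

* ppm sign convention: $\Delta\omega = \omega_{minor} - \omega_{dominant}$,
  positive downfield; the exchange peak appears at a carrier offset of
  $+\Delta\omega$.
* Rates above $10^9$ s⁻¹ are rejected as outside the propagator's validated
  range rather than silently computed.
* Eigendecomposition is the primary solver everywhere; conditioning
  thresholds ($10^{-13}$ reciprocal condition) trigger the matrix-exponential
  or RK4 fallbacks.
* Reduced-χ² acceptance band for simulated-data fits: [0.5, 2.0].
* Temperature fixed at 298.15 K; energies in kcal/mol.
* The diffusion-limited protonation constant defaults to
  $6\times10^{11}$ M⁻¹s⁻¹ everywhere a constraint needs it; $7\times10^{11}$
  is an equally defensible alternative and can be passed explicitly.

# Limitations

* Fits assume a single shared $R_1$/$R_2$ pair per probe; genuinely
  state-dependent relaxation biases fitted exchange parameters.
* The three-state fit shares relaxation rates across pH within a probe;
  datasets acquired at different fields per pH should be fitted per field.
* The five-state model fixes the Hill coefficient at 1; cooperative
  multi-proton transitions are out of scope.
* Monte Carlo SDs are conditional on the fitted noise model; if reported SDs
  misstate the real scatter, the uncertainties inherit that misstatement.
* No ionic-strength or activity corrections: pH enters as
  $[\mathrm{H}^+] = 10^{-\mathrm{pH}}$.
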