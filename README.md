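# protex

Simulation and fitting of NMR chemical-exchange data for sparsely populated,
protonation-coupled conformational states of nucleic acids.

Many RNAs transiently adopt alternative secondary structures ("excited
states") with populations well under 1% and lifetimes of milliseconds. When
such a state is stabilized by protonation of a nucleobase — for example a
wobble C⁺–C mismatch — its population becomes pH dependent, but the coupling
between protonation and conformational change also depresses the apparent pKa
of the transition far below the intrinsic pKa of the protonated site, often
below the experimentally accessible pH range. `protex` implements the
quantitative machinery needed to detect and dissect such states from
rotating-frame relaxation dispersion (R1ρ) and chemical exchange saturation
transfer (CEST) measurements:

- **Forward models.** Bloch–McConnell evolution of the full 3N-dimensional
  magnetization for 2- and 3-state exchange, with the experiment's own
  estimator (projection onto the initial effective-field axis at five evenly
  spaced delays, mono-exponential fit) for R1ρ, and saturation-profile
  simulation with Gauss–Hermite averaging over B1 inhomogeneity for CEST.
- **Inverse problems.** Global weighted least-squares fits sharing the
  minor-state population `p` and exchange rate `k_ex` across probes;
  a constrained three-state fit of the linear topology GS ⇌ GS⁺ ⇌ ES2⁺ in
  which the protonation step is pinned at the diffusion limit,
  `k_ex,prot = k_prot([H⁺] + 10^(−pKa,GS))`; parametric Monte Carlo parameter
  uncertainties; and wAIC/wBIC model selection for CEST profiles fitted with
  and without exchange.
- **Thermodynamics.** The five-state proton-coupled model
  ES1⁺ ⇌ ES1 ⇌ GS ⇌ ES2 ⇌ ES2⁺, with
  `pKa_apparent = pKa_intrinsic + log10(K_conf)`, apparent-population curves
  versus pH, free-energy penalties `ΔG = −RT ln(p_ES2 + p_ES2⁺)`, weighted
  fitting with multi-start optimization, and a pKa degeneracy scan.
- **Kinetics.** The explicit 3×3 rate-matrix simulator for
  ES1⁺ ⇌ GS ⇌ ES2⁺ solved by eigendecomposition, reduction of traces to
  apparent two-state observables, linear fits `k_forward = k_on[H⁺]`,
  `k_reverse = k_off`, and the mechanism-discrimination toolbox (induced fit
  versus conformational selection, kinetic solvent isotope effects, mutant
  fold-change predictions).
- **Synthetic data.** Seeded generators for R1ρ tables, CEST grids, and
  pH-population series with the statistical structure the analyses assume, so
  the whole pipeline is testable without spectrometer data.

Everything takes and returns plain tibbles, so the pieces chain with the pipe;
fitted objects support `tidy()`, `glance()`, and `autoplot()`.

## Worked example

Simulate a three-probe R1ρ dataset at pH 5.4 from a two-state model with a
1.7% minor state exchanging at 562 s⁻¹, fit it globally, and inspect the
thermodynamic consequences:

```r
library(protex)

probes <- tibble::tibble(probe = c("U38-N3", "U23-C6", "A35-C8"),
                         larmor_mhz = c(60.8, 150.9, 150.9))
dw <- c("U38-N3" = 3.2, "U23-C6" = -1.2, "A35-C8" = 1.8)
truth <- two_state_model(p_minor = 0.017, k_ex = 562,
                         dw_ppm = cbind(GS = c(0, 0, 0), ES = dw))

dat <- gen_r1rho_dataset(truth, relax_params(2, 20), probes,
                         grid = r1rho_grid(powers_hz = c(100, 300, 1000)),
                         noise = noise_model(0.02, seed = 7), ph = 5.4)

fit <- fit_two_state_global(dat, probes, dw_init = dw, n_mc = 500, seed = 1)
dplyr::filter(tidy(fit), term %in% c("p_minor", "k_ex"))
#> # A tibble: 2 × 4
#>   term    estimate std.error fixed
#>   <chr>      <dbl>     <dbl> <lgl>
#> 1 p_minor   0.0164  0.000595 FALSE
#> 2 k_ex    549.     35.0      FALSE
```

The fit recovers the generating population and exchange rate within their
Monte Carlo uncertainties. The thermodynamic layer then converts such pH
series into intrinsic quantities:

```r
params <- thermo_params(kconf_es2 = 0.9e-3, pka_es2 = 7.1,
                        kconf_es1 = 0.01, pka_es1 = 7.5)
apparent_pka(7.1, 0.9e-3)
#> [1] 4.054243
population_es2(5.4, params) / population_es2(7.0, params)
#> [1] 10.20228
dg_penalty(7.4, params)
#> [1] 3.928481
```

A 7.1 intrinsic pKa is depressed to an apparent pKa of ~4.05 by the ~4.1
kcal/mol conformational penalty (−RT ln K_conf), and the apparent minor-state
population rises ~10-fold between pH 7.0 and pH 5.4 — the signature of a
protonated excited state.

See the methods vignette (`vignettes/proton-coupled-exchange.Rmd`) for the
model definitions, the estimator and optimizer choices, and what the
synthetic-data suites do and do not demonstrate.

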