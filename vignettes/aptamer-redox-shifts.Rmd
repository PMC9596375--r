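---
title: "Measuring aptamer-induced shifts in flavin reduction potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring aptamer-induced shifts in flavin reduction potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptaredox)
```

## The model

An aptamer that binds the oxidized form of a flavin more tightly than
the reduced form changes the bound cofactor's midpoint reduction
potential. Writing the Gibbs energies around the closed cycle
free-ox → bound-ox → bound-red → free-red, with
ΔG_bind = RT·ln(K_d) for each oxidation state and
ΔG_red = −nF·E_m for each binding state, the cycle condition gives

$$\Delta E_m \;=\; E_m^{bound} - E_m^{free} \;=\; -\frac{RT}{nF}\,
  \ln\!\frac{K_d^{red}}{K_d^{ox}}.$$

All potentials in this package are millivolts vs the standard hydrogen
electrode; the flavin couple is treated as a single two-electron
quinone/hydroquinone conversion (n = 2), justified operationally by
the absence of the one-electron semiquinone's ~600 nm absorbance
(`semiquinone_check()`). Both directions of the cycle relation are
exposed (`kd_ratio_from_delta_em()`, `delta_em_from_kd()`) and are
exact mutual inverses.

## The dual-indicator equilibration assay

The measurement co-reduces the flavin (or aptamer–flavin complex) with
a reference dye of known potential — anthraquinone-2-sulfonate (AQS,
E_m = −225 mV) or phenosafranin (PSF, −252 mV) — using xanthine /
xanthine oxidase as a slow electron source and methyl viologen as a
mediator. Because delivery is slow relative to inter-couple electron
exchange, both couples sit at one solution potential $E$ at all times,
and each species' "Nernst term" $(RT/nF)\ln([ox]/[red])$ equals
$E - E_m$ for that species. Plotting the two terms against each other
over the course of the reduction therefore gives a straight line, and
the displacement between the axes is the difference of midpoint
potentials.

**Axis and sign convention.** The package regresses the *dye's* terms
(y) on the *flavin's* (x). With that orientation the intercept is read
at the point where the flavin term crosses zero (i.e. where
$E = E_m^{flavin}$), so

$$b \;=\; E_m^{flavin} - E_m^{dye}, \qquad
  E_m^{flavin} = E_m^{dye} + b,$$

and, when one shared prefactor is applied to both axes (the
potentiometric-plot convention: a single printed constant such as
12.5 mV), the slope equals $n_{dye}/n_{flavin}$ — exactly 1 for the
matched two-electron pairs used here. The package applies the
intercept rule $E_m = E_m^{dye} + b$; note that the opposite axis
assignment (flavin on y) would negate the intercept. A property test
with a hypothetical one-electron dye (slope 0.5) pins the convention
down.

**Temperature.** The default is 295 K (room-temperature assay).
The familiar 12.5 mV axis constant corresponds to RT/2F at ≈290 K;
both are available by setting `thermo_conditions(temperature = ...)`,
and the temperature enters only through the prefactor.

## What the simulator emulates — and what it does not

`simulate_assay()` generates the raw object of the assay: a time ×
wavelength absorbance matrix (290–750 nm, every minute, 120–180 min)
with 20 µM flavin and 20 µM dye. Its stated world:

* **Electron delivery** is pseudo-zero-order at `delivery_rate`
  (default 0.8 µM-equivalents/min), capped at the donor capacity
  (700 µM xanthine × 2 e⁻ = 1400 µM-eq, far above the ~80 µM-eq the
  two indicators accept, so full reduction is always reached).
* **Equilibration** is exact: at each timepoint a bisection solve
  (tolerance 10⁻⁹ µM-eq) finds the unique shared potential at which
  the summed reduced equivalents equal those delivered. The mediator
  (E_m ≈ −446 mV) holds a negligible share in the fitted window and is
  modeled as spectrally and thermodynamically silent; the
  glucose-oxidase oxygen scrub is assumed perfect.
* **Spectra** are sums of Gaussian bands. The sources report peak and
  isosbestic *wavelengths* but no molar absorptivities and no
  reduced-state spectra, so amplitudes are simulator conventions
  chosen once to approximate published extinction scales (oxidized
  FAD ε(450) ≈ 11.3 mM⁻¹cm⁻¹, near-UV band ≈ 9.2). Reduced flavin is
  bleached at 400–500 nm with a residual ~343 nm band; reduced AQS and
  leuco-PSF are near-colorless in their measurement windows. Declared
  isosbestic points (flavin 335 nm, AQS 355 nm) are enforced exactly
  by rescaling the reduced envelope. Bound-flavin presets shift the
  visible peak to 456/458 nm and add symmetric ±26 nm shoulders.
* **Noise** is i.i.d. Gaussian in absorbance with a seeded generator;
  identical seeds give bit-identical output.

Not modeled: enzyme kinetics, oxygen leaks, photobleaching,
semiquinone intermediates, baseline drift, and wavelength-correlated
noise. A green recovery test therefore establishes that the *analysis
chain is faithful to the stated physics*, not that it is robust to
every instrumental pathology; the stochastic acceptance property
(±2 mV in ≥95% of 100 replicates at 0.003 AU noise) probes only the
white-noise axis.

## The inference pipeline and its tunables

`run_em_pipeline()` chains, per replicate:

1. **Plateau detection** (`detect_plateau`): earliest frame after
   which the max frame-to-frame change stays below `plateau_tol`
   (default 10⁻³ AU) for `plateau_window` (5) frames. With noise above
   the tolerance no plateau is declared and the final frame is used
   with a warning — the correct anchor whenever the run comfortably
   outlasts delivery saturation, as the default schedule guarantees.
2. **Fraction traces** (`fraction_oxidized_trace`): absorbance at a
   single wavelength (band-averaging over ±`band_halfwidth` nm is
   available for noisy data) anchored so the first frame is exactly
   100% oxidized and the plateau exactly 0%. AQS assays read the dye
   at 335 nm (flavin isosbestic) and the flavin at 355 nm (AQS
   isosbestic). PSF assays read the dye at 540 nm and the flavin at
   456 nm after subtracting the dye's fraction-weighted basis
   contribution (`subtract_reference_contribution`) — the physically
   complete form of the subtraction, preferred over rescaling a fixed
   reference spectrum because it remains exact at every mixing ratio.
3. **Nernst regression** (`fit_nernst`): ordinary least squares with
   points masked out when either species' fraction leaves
   `mask_bounds` (default [0.05, 0.95]); the log terms diverge at the
   anchors, and whether the original procedure masked near-anchor
   points is unstated — the default is our convention, and a
   documented property shows tightening it to [0.10, 0.90] moves a
   noiseless answer by < 0.1 mV. Total least squares
   (`method = "orthogonal"`) is available since both axes carry error
   under noise.
4. **Averaging**: replicate E_m values are averaged; the reported
   spread is the sample standard deviation (`NA` for a single run).

## Numerical and design choices

* Potentials stay in mV everywhere; volts appear only inside
  `gibbs_from_em()`.
* The bisection bracket spans all couples' E_m ± 45 prefactors, so
  endpoint fractions (0 or 1) are handled by exact short-circuits
  rather than by the solver.
* The ITC model (shared by `simulate_itc()` and `fit_one_site_itc()`)
  is the exact single-site quadratic with per-injection dilution
  `d = 1 − v/V0` and displaced-volume heat correction; the baseline is
  a single constant dilution offset, separately measurable, rather
  than an instrument-specific drift model. Kd is fitted on a log scale
  with multistart over six decades; ΔS is derived from
  ΔG = RT·ln(K_d) = ΔH − TΔS, so thermodynamic consistency is exact by
  construction. Fits with c-values outside [1, 1000] warn that Kd is
  poorly determined.
* `fit_hill()` fixes B_max = 1 (the titrations are normalized to
  fraction bound) and multistarts the Hill slope at 0.5/1/2.
* `fit_inline_probing()` shares one B_max between the oxidized and
  reduced curves; a reduced curve flat at zero (< 2% of the oxidized
  amplitude) yields a *censored* K_d with a lower bound at the largest
  probed concentration instead of an astronomically large point
  estimate.
* `delta_lambda_max()` reports the plain difference of argmax
  wavelengths in a 400–520 nm window (avoiding the near-UV peak).
  Published Δλ_max labels are not always the plain difference of the
  quoted peak positions (450 → 456 nm appears as "+8 nm"); the
  implementation does not attempt to reproduce that arithmetic and
  documents the discrepancy instead.
* A reported shift for the parent aptamer–FAD complex (−223 mV,
  quoted as ΔE_m = −11 mV against a free value of −209 mV) likewise
  differs from the plain difference (−14 mV); `run_em_pipeline()`
  always reports the plain difference `e_m − em_free`.

## Limitations

The simulator's spectral amplitudes are conventions, so absolute
absorbances (and hence signal-to-noise at a given `noise_sd`) match
real instruments only in order of magnitude. One-electron couples are
supported in the thermodynamics and the simulator but the pipeline's
intercept rule assumes matched electron counts; for mixed counts the
intercept scales by $n_{dye}/n_{flavin}$ and must be corrected by the
caller. pH dependence of E_m, metal-ion effects and semiquinone
thermodynamics are out of scope.
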