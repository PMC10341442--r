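---
title: "Models and methods: hemoglobin unmixing, storage kinetics and the ROS balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: hemoglobin unmixing, storage kinetics and the ROS balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcspectra)
```

This vignette is the package's own account of the science it implements: the
models, their assumptions, the numerical choices behind the fits, and what the
synthetic-data tests do and do not demonstrate about real measurements.

## 1. The spectral model

A dilute red-blood-cell suspension measured between 500 and 700 nm absorbs
through three heme species and scatters through two mechanisms. The package
models the absorbance at wavelength $\lambda$ as

$$D(\lambda) = \varepsilon_{HbO_2}(\lambda)\,C_{HbO_2}L
            + \varepsilon_{Hb}(\lambda)\,C_{Hb}L
            + \varepsilon_{MetHb}(\lambda)\,C_{MetHb}L
            + M + S\lambda^{-4},$$

with molar absorptivities $\varepsilon$ in L·mmol⁻¹·cm⁻¹, concentrations $C$
in mmol/L and the optical path $L$ in cm, so each Beer–Lambert term is a
dimensionless absorbance. $M$ (AU) absorbs wavelength-flat contributions —
scattering by whole cells, which are much larger than the wavelength, and any
cuvette/blank drift — and is therefore left unconstrained in sign. $S$
(AU·nm⁴) scales the Rayleigh $\lambda^{-4}$ term from sub-wavelength membrane
roughness and is constrained non-negative, as are the three concentrations.

**Assumptions.** Absorbances add linearly (no heme–heme interaction, no
inner-filter effects at the dilutions used); the scattering background is
fully described by $M + S\lambda^{-4}$; the extinction basis matches the
instrument's wavelength calibration. Carboxyhemoglobin and other minor
derivatives are not modeled.

### Fitting

The model is *linear* in all five unknowns, so "nonlinear curve fitting" is
unnecessary: `fit_spectrum()` solves a sign-constrained linear least-squares
problem. With only four sign-constrained parameters, the exact solution is
found by enumerating all $2^4$ candidate active sets, solving each reduced
problem by QR, and keeping the feasible candidate with the smallest residual
sum of squares — the global constrained optimum is always among them because
it is the unconstrained minimizer of its own active face. This is
deterministic: no starting values, no convergence tolerances, no local
minima. Ties (identical SS) resolve deterministically over a fixed
enumeration that considers the fully unconstrained candidate first.

Two numerical details matter:

* **Column scaling.** Raw $\lambda^{-4}$ values near $10^{-11}$ nm⁻⁴ would
  ruin the conditioning of the normal equations, so the internal design column
  is $(\lambda_{ref}/\lambda)^4$ with $\lambda_{ref} = 550$ nm, and $S$ is
  rescaled back to AU·nm⁴ on output.
* **Standard errors.** SEs come from
  $\hat\sigma^2 (X^\top X)^{-1}$ of the design restricted to the parameters
  *not* pinned at a bound ($\hat\sigma^2$ = SS/(n − p_free)). A parameter at
  the zero bound has no two-sided curvature, so it reports `NA` rather than a
  misleading number; the printed output marks it "(at bound)".

Spectra are cropped to the 500–700 nm window, never resampled; the basis is
aligned to the measured grid by linear interpolation (`resample_basis()`),
chosen over splines because linear interpolation is monotone between knots
and cannot overshoot below zero. Degenerate designs (collinear basis columns)
raise an error naming the offending columns instead of returning arbitrary
coefficients.

Whether the non-negativity convention matters can be checked per fit: the
result records `nonneg_constrained = TRUE` and the set of pinned parameters.

### Path length and units

The measurement geometry is a 1 mm layer, so `path_length_cm` defaults to
0.1 cm. With absorptivities in L·mmol⁻¹·cm⁻¹ this puts fitted concentrations
in mmol/L, a physiologic scale for heme in dilute suspensions (the generator's
default of 0.6 mmol/L total heme yields peak absorbances near 1 AU, matching
a suspension at roughly 0.013 hematocrit).

## 2. Hemolysis

`hemolysis_pct()` computes $K = 100\, d\, C^{sup}_{tot} / C^{susp}_{tot}$ %,
where each total is the sum of the three fitted concentrations from the
corresponding spectrum and $d$ is a dilution ratio defaulting to 1 (no
dilution correction; the parameter exists because supernatant and suspension
need not share hematocrit-driven scattering, and a protocol may dilute the
supernatant before measuring). Both spectra are fitted with the full
five-parameter model — the supernatant, though cell-free, still gets the
scattering terms, which simply fit to near zero when the background is flat.
$K$ may exceed 100% under noise; it is reported as computed, never clipped
silently.

## 3. Deoxygenation kinetics

Closed-tube storage depletes oxygen and the deoxyhemoglobin percentage rises
along a sigmoid. `fit_cdf()` fits

$$y(t) = \mathrm{base} + (\mathrm{plateau}-\mathrm{base})\,
  \Phi\!\left(\frac{t - t_m}{\sigma}\right),$$

a four-parameter Normal-CDF transition: `base` and `plateau` (%, bounded to
[0, 100] and fitted, not pinned at the observed extremes — the result records
this convention), midpoint $t_m$ (days) and width $\sigma$ (days, positive).
Per-day standard deviations, when available, enter as $1/\mathrm{sd}^2$
weights.

**Optimization.** The fit is Levenberg–Marquardt with box bounds
(`minpack.lm::nlsLM`) from a deterministic, data-driven start (base = min y,
plateau = max y, $t_m$ = interpolated half-rise crossing, $\sigma$ = span/4),
plus a ladder of deterministic restarts. Because a near-step transition
($\sigma \to 0$) makes the $t_m$ and $\sigma$ gradient columns vanish —
Levenberg–Marquardt then cannot even build its model object — the fitter
*always* also runs a profiled search: the model is linear in (base, plateau)
given $(t_m, \sigma)$, so those two are solved exactly on a 41×25
$(t_m, \log\sigma)$ grid and the best cell is polished by bounded BFGS. The
better of the two routes (by weighted SS) wins; when the profiled route wins
it is re-polished by Levenberg–Marquardt for an exact covariance where
possible, and otherwise SEs come from the Gauss–Newton Hessian, with `NA` in
degenerate directions (e.g. $\sigma$ at its bound). Flat series raise a
degenerate-series error: a transition model has nothing to estimate there,
and the open-tube (normoxemic) conditions are expected to trip this by
design.

**The formation rate.** The rate of deoxyhemoglobin formation is defined here
as $1/t_m$ (day⁻¹), the reciprocal midpoint time: transitions at 11.0 and
17.7 days give 0.09 and 0.06 day⁻¹ at the two-decimal reporting precision.
This is the simplest convention consistent with those paired values; the
natural alternative — the maximum slope of the fitted curve,
$(\mathrm{plateau}-\mathrm{base})\,\phi(0)/(100\,\sigma)$ per day — is
deliberately exposed as a separate, clearly named quantity
(`rate_max_slope()`) rather than folded into `rate()`.

**"Time to 50% Hb."** Two readings coexist: the CDF midpoint $t_m$ (50% *of
the transition*), and the absolute 50-percentage-point level. `fit_cdf()`
reports both — `tm_days` always, and `t50_abs_days` (the analytic inversion
$t = t_m + \sigma\,\Phi^{-1}((50-\mathrm{base})/(\mathrm{plateau}-\mathrm{base}))$)
whenever 50% lies strictly inside (base, plateau), `NA` otherwise.
`time_to_threshold()` generalizes the inversion to any reachable level.

## 4. The ROS balance model

The oxidant system generates reactive oxygen species at $F_{os}(C) = aC^2$
and the antioxidant system removes them at $F_{aos}(C) = bC$, with an
oxygen-independent baseline $F_0$, giving the net quadratic

$$\frac{dC_{ROS}}{dt} = F(C) = aC^2 - bC + F_0 .$$

For $a > 0$ the minimum is at $C_{opt} = b/(2a)$ with
$F_{min} = F_0 - b^2/(4a)$: ROS production is lowest at a mildly hypoxemic
oxygen level, and rises toward both anoxemia ($C \to 0$, where the
antioxidant term has nothing to work with but $F_0$ persists) and normoxemia
(where the quadratic oxidant term dominates). The model is explicitly
qualitative: $C$ stays in arbitrary units tracking oxygen pressure PO2
(mmHg), no unit conversion is attempted, and the reference parameterization
$a = 0.02$, $b = 2$, $F_0 = 55$ gives $C_{opt} = 50$, $F_{min} = 5$. The two
subsystem rates are exposed separately (`ros_oxidant_rate()`,
`ros_antioxidant_rate()`) so the balance equation itself is directly
testable. Annotating normoxemia/anoxemia reference points on the curve takes
user-supplied coordinates only — the model fixes none.

Fitting $(a, b, F_0)$ to measured ROS data is out of scope: the model here is
a closed-form analysis tool, not an estimator.

## 5. The synthetic-data generator

`trajectory_config()` + `make_series()` emulate a storage study's structure:

* **Schedule and design.** Sampling on days 0, 7, 14, 21, 29; conditions are
  tube (closed = developing hypoxemia/anoxemia, open = normoxemia) ×
  storage-solution strength (0/30/60/100%), eight conditions, 40 spectra.
* **Deoxyhemoglobin.** A Normal-CDF rise from 20% to 85% — the start-of-storage
  state is ~80% HbO2 / ~20% Hb — with condition-specific midpoints: 11 days
  (0% StS), 15.2 days (30%), 17.7 days (60%); the 100% StS and all open-tube
  courses stay flat at the day-0 level. The transition width is not separately
  reported anywhere usable, so the generator fixes $\sigma = 3$ days, a value
  that makes the day-7 sample sit on the early rise and day-14 near the
  plateau, consistent with a "sharp increase after day 7".
* **Methemoglobin.** Zero until day 7, then a linear ramp to 5% (60% StS) or
  25% (100% StS) at day 29 — linear because only the onset day and final level
  are specified, and a ramp is the simplest shape consistent with both.
* **Oxyhemoglobin.** The remainder to 100%; configurations implying negative
  HbO2 are rejected at construction.
* **Rendering.** Fractions × total heme (default 0.6 mmol/L) go through the
  *same* design-matrix code path the fitter uses (`forward_absorbance()`),
  plus $M = 0.05$ AU, $S = 2\times10^9$ AU·nm⁴ and additive homoscedastic
  Gaussian absorbance noise (default SD 0.005 AU — ordinary spectrophotometer
  noise; no instrument noise model is specified, and additive-in-AU is the
  standard assumption). All randomness is seeded; a generator is a pure
  function of (config, seed), and the RNG state of the session is left
  untouched.

`make_hemolysis_pair()` renders a supernatant holding `k_true`% of the
suspension's heme, so the hemolysis estimator can be validated by round trip.

**What passing tests show — and what they don't.** Because generator and
fitter share one forward model, noise-free round trips prove the inversion is
exact and noisy recovery quantifies estimator variance under the stated noise
model. They do *not* validate the model against real cells: real spectra may
violate the $M + S\lambda^{-4}$ scattering form (e.g. hematocrit-dependent
multiple scattering), real absorptivities differ from the synthetic
Gaussian-peak basis shipped as a stand-in (use `load_basis()` with a measured
table for real work), real noise is neither homoscedastic nor purely
additive, and real MetHb kinetics need not be linear. The package's claims
about real data are therefore structural (the estimator is exact and
unbiased under its assumptions), not empirical.

## 6. Problem sizes and determinism

The test suite and the acceptance script run at desk scale as a matter of
design: 201-point spectra (500–700 nm at 1 nm), 40-spectrum studies, 100
Monte-Carlo replicates for recovery studies, 200 for hemolysis bias, and a
$10^4$-point lattice oracle for the constrained-fit cross-check. Every
stochastic step takes an explicit integer seed, derived seeds stay below
$2^{31}$, and repeated runs are byte-identical (verified for the CLI
pipeline).

## 7. Known limitations

* Only the three classical derivatives; no carboxyhemoglobin, no
  sulfhemoglobin.
* One scattering law; no turbidity models beyond $M + S\lambda^{-4}$, no
  multi-path-length fitting.
* The kinetics module fits the deoxyhemoglobin course only; MetHb levels are
  reported per day but no kinetic model is fitted to them.
* The supply/demand oxygen gap of the ROS discussion has no operational
  definition and is not computed.
* SEs of the unmixing fit are conditional on the selected active set; model
  uncertainty about *which* parameters sit at zero is not propagated.
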