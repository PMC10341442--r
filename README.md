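# rbcspectra

Quantitative spectroscopy of stored red blood cells: hemoglobin-derivative
unmixing, hemolysis quantification, deoxygenation kinetics, and an
oxidant/antioxidant balance model of ROS production.

## The problem

Red blood cells stored in closed containers progressively deplete their
oxygen: oxyhemoglobin (HbO2, absorption peaks at 542 and 577 nm) converts to
deoxyhemoglobin (Hb, peak at 555 nm), and — depending on the storage medium —
part of the heme oxidizes to methemoglobin (MetHb, peak at 630 nm). The
visible absorbance spectrum of a dilute RBC suspension between 500 and 700 nm
therefore carries the full redox state of the sample, on top of a scattering
background. This package turns such spectra into numbers:

1. **Spectral unmixing** (`fit_spectrum`). The measured absorbance is modeled
   as a multicomponent Beer–Lambert mixture plus two scattering terms:

   D(λ) = ε_HbO2(λ)·C_HbO2·L + ε_Hb(λ)·C_Hb·L + ε_MetHb(λ)·C_MetHb·L + M + S/λ⁴

   with molar absorptivities ε (L·mmol⁻¹·cm⁻¹), concentrations C (mmol/L),
   path length L (cm), a constant offset M (AU, large-particle scattering and
   blank drift) and a Rayleigh term S/λ⁴ (AU·nm⁴, membrane-scale roughness).
   The model is linear in all five unknowns, so the fit is solved as
   sign-constrained linear least squares (concentrations and S non-negative,
   M free) by exact active-set enumeration — deterministic, no starting
   values, no local minima. Results are reported as value ± SE with R².

2. **Hemolysis** (`hemolysis_pct`). Free hemoglobin in the supernatant over
   total hemoglobin in the suspension:
   K = 100 · C_tot(supernatant) / C_tot(suspension) %, each total being the
   sum of the three fitted derivative concentrations.

3. **Deoxygenation kinetics** (`fit_cdf`, `rate`). The Hb percentage over
   storage days follows a Normal-CDF transition
   y(t) = base + (plateau − base)·Φ((t − tm)/σ); the fitted tm is the time to
   the transition midpoint and the formation rate is reported as 1/tm day⁻¹
   (a transition at 11.0 days gives 0.09 day⁻¹, one at 17.7 days gives
   0.06 day⁻¹).

4. **ROS balance model** (`ros_params`, `ros_optimum`). Net production of
   reactive oxygen species as a function of oxygen concentration C is modeled
   as F(C) = a·C² − b·C + F0 (oxidant system a·C², antioxidant system b·C,
   baseline F0). For a > 0 the rate is minimal at C_opt = b/(2a) with
   F_min = F0 − b²/(4a): a mildly hypoxemic optimum between anoxemia and
   normoxemia.

A seeded synthetic-data generator (`trajectory_config`, `make_series`,
`make_hemolysis_pair`) renders whole storage studies through the same forward
model the fitter inverts, so every stage is testable by parameter recovery.
The shipped extinction table (`inst/extdata/extinction_synthetic_500_700nm.csv`)
is a **synthetic** Gaussian-peak stand-in with the literature band positions,
generated by `synth_basis()`; real absorptivity tables load via `load_basis()`.

## Worked example

```r
library(rbcspectra)

basis <- synth_basis()                       # or load_basis("<your table>.csv")

# simulate one storage condition and unmix its day-14 spectrum
tr <- make_trajectory(trajectory_config(noise_sd_au = 0.005, seed = 42))
sp <- make_spectrum(c(tr$hbo2_pct[3], tr$hb_pct[3], tr$methb_pct[3]), 0.6,
                    basis, m = 0.05, s_au_nm4 = 2e9, noise_sd = 0.005,
                    seed = 42, day = 14)
fit_spectrum(sp, basis)
#> <unmix_result> concentrations (mmol/L), value ± SE
#>   C_HbO2 : 0.1515 ± 0.0017
#>   C_Hb   : 0.4487 ± 0.0021
#>   C_MetHb: 0 (at bound)
#>   M      : 0.04903 ± 0.00099 AU
#>   S      : 2.089e+09 ± 1.2e+08 AU·nm⁴
#>   R² = 0.99967
```

The fitted concentrations recover the simulated day-14 state (74.7% Hb,
25.3% HbO2 of 0.6 mmol/L total heme at L = 0.1 cm) with MetHb correctly
pinned at zero. A whole study then yields the transition kinetics:

```r
spectra <- make_series(default_study(seed = 42), basis)
tab <- batch_fit(spectra, basis)
sub <- tab[tab$tube == "closed" & tab$sts_pct == 0, ]
fit0 <- fit_cdf(kinetic_series(sub$day, pmin(pmax(sub$hb_pct, 0), 100)))
fit0
#> <cdf_fit> y(t) = base + (plateau - base) * pnorm((t - tm)/sigma)
#>   base    = 20.12 ± 1.03 %
#>   plateau = 84.37 ± 0.73 %
#>   tm      = 11.00 ± 0.23 days
#>   sigma   = 2.90 ± 0.19 days
#>   rate    = 0.09 / day   R² = 0.9997

ros_optimum(ros_params(a = 0.02, b = 2, f0 = 55))
#> <ros_optimum> C_opt = 50, F_min = 5
```

The closed-tube 0% storage-solution condition deoxygenates with a midpoint
near day 11, i.e. a formation rate of 0.09 day⁻¹; the ROS balance at the
reference parameters has its minimum at an oxygen level of 50 (arbitrary
units tracking PO2 in mmHg) with a minimal rate of 5.

## Command line

The same workflow is scriptable via `exec/rbcspectra` (or `run_cli()` in R):

```sh
rbcspectra simulate  --out spectra/ --seed 1
rbcspectra unmix     --spectra spectra/ --out fits.csv
rbcspectra report    --spectra spectra/ --out report/
rbcspectra ros-curve --a 0.02 --b 2 --f0 55 --out curve.csv
```

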