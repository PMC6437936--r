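# membranalysis

Quantitative analysis of model lipid membranes that display
liquid-ordered/liquid-disordered (l<sub>o</sub>/l<sub>d</sub>) phase
coexistence — the ternary phosphatidylcholine/cholesterol mixtures used
throughout membrane biophysics to mimic the lipid component of cell
membranes — and of how membrane-active compounds (e.g. the propolis-derived
phenolic artepillin C) reshape them. The package is written for membrane
biophysicists who combine three bench techniques on one sample series and
want a single, tested, scriptable pipeline:

* **SAXS global analysis** of vesicle suspensions. The measured intensity is
  modeled as a mixture of multilamellar and unilamellar scatterers,

  *I(q) = s[(1 − N<sub>UV</sub>) S(q) |F(q)|²/q² +
  N<sub>UV</sub> |F(q)|²/q²] + b*,

  with a symmetric three-Gaussian electron-density form factor F(q), a
  modified Caillé structure factor S(q) (stack size N, repeat d, bending
  fluctuation η), and N<sub>UV</sub> the fraction of positionally
  non-correlated (unilamellar) vesicles. Membrane thickness follows
  *d<sub>B</sub> = 2(z<sub>H</sub> + 2σ<sub>H</sub>)*.
* **DSC thermotropics**: chord baseline subtraction, transition temperature
  T<sub>m</sub>, width at half height T<sub>1/2</sub>, calorimetric enthalpy
  ΔH<sub>c</sub>, van't Hoff enthalpy *ΔH<sub>VH</sub> ≅ 4RT<sub>m</sub>²/
  T<sub>1/2</sub>*, and the cooperative unit CU = ΔH<sub>VH</sub>/ΔH<sub>c</sub>
  with replicate-scan statistics.
* **Laurdan GP imaging** of giant unilamellar vesicles: G-factor-calibrated
  generalized polarization *GP = (I₄₄₀ − G·I₄₉₀)/(I₄₄₀ + G·I₄₉₀)*,
  equatorial-ring segmentation into coexisting phases, and per-phase GP
  time series.

Seeded synthetic-data generators for all three modalities
(`simulate_saxs_curve()`, `simulate_thermogram()`, `simulate_guv_frames()`)
embed their ground truth, so every estimator is validated by recovery tests
without external data.

## Worked example

Simulate a 52%-unilamellar suspension in the regime of an extruded
DOPC/DPPC/cholesterol 23:47:30 preparation, fit it blind, and read off the
recovered structure:

```r
library(membranalysis)

truth <- saxs_preset("saxs_control")   # d = 65.8 A, N_UV = 0.52, d_B = 50.2 A
sim   <- simulate_saxs_curve(truth, noise_fraction = 0.01, seed = 1)
fit   <- fit_curve(sim$curve)
fit
#> <saxs_fit>  chi2_red = 0.9341  on 300 points
#>   d_B   = 50.20 +/- 0.01 A
#>   N_UV  = 52.1 %
#>   d     = 65.80 A, N_layers = 5, eta = 0.0998
```

The fit recovers the bilayer thickness d_B (50.2 Å), the unilamellar
percentage (52%), and the lamellar repeat d (65.8 Å) of the generating
model; `tidy(fit)` gives per-parameter estimates and standard errors,
`autoplot(fit)` overlays model and data.

The same round trip for calorimetry — a two-state endotherm whose
conventional factor-4 analysis yields the familiar numbers:

```r
sim_dsc <- simulate_thermogram(Tm = 305.75, dH_cal = 1.4, dH_vH_true = 66.8)
analyze_thermogram(sim_dsc$thermogram, T_low = 285, T_high = 325)
#> <dsc_transition>
#>   Tm      = 305.65 K (32.5 C)
#>   T_1/2   = 9.77 K
#>   dH_cal  = 1.38 kcal/mol
#>   dH_vH   = 76 kcal/mol
#>   CU      = 55
```

Here T<sub>m</sub> ≈ 32.5 °C, ΔH<sub>c</sub> ≈ 1.4 kcal/mol and CU ≈ 54
characterize the broad endotherm of a cholesterol-rich l<sub>o</sub> phase;
note the factor-4 convention reports ΔH<sub>VH</sub> ≈ 76 kcal/mol for a
true two-state enthalpy of 66.8 (the documented 4/3.5255 over-report).

GP imaging runs end to end from frames to a tidy per-phase table:

```r
guv <- simulate_guv_frames(n_frames = 6, step_frame = 3, step_delta_gp = 0.05)
gp_timeseries(guv$frames, g_factor = 1, min_total_intensity = 100)
# one row per time point: gp_lo_mean ~ 0.45, gp_ld_mean ~ 0.05, and a +0.05
# step in every region from frame 3 onward
```

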