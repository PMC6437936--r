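---
title: "Models and methods behind membranalysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind membranalysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membranalysis)
```

membranalysis quantifies how membrane-active compounds reshape model lipid
bilayers, using the three complementary observables most often combined in
this field: small-angle X-ray scattering (SAXS) of vesicle suspensions,
differential scanning calorimetry (DSC) of the thermotropic phase
transition, and laurdan generalized-polarization (GP) imaging of giant
unilamellar vesicles (GUVs). The motivating system is a ternary
DOPC/DPPC/cholesterol 23:47:30 mixture exhibiting liquid-ordered
(l~o~)/liquid-disordered (l~d~) coexistence, challenged with artepillin C, a
prenylated phenolic acid from Brazilian green propolis. This vignette
explains the models, the tunable parameters, the synthetic-data generators
used for validation, and the numerical choices that were genuinely open.

## SAXS: global analysis of vesicle suspensions

Extruded vesicle suspensions are rarely purely unilamellar; residual
oligolamellar stacks produce quasi-Bragg peaks on top of the diffuse bilayer
scattering. The model intensity treats the suspension as a mixture of
positionally correlated and non-correlated bilayers:

$$ I(q) = s\left[(1 - N_{UV})\,S(q)\,\frac{|F(q)|^2}{q^2}
        + N_{UV}\,\frac{|F(q)|^2}{q^2}\right] + b $$

where $N_{UV}$ is the fraction of positionally non-correlated (unilamellar)
scatterers, $1/q^2$ is the Lorentz factor for randomly oriented planar
scatterers, and $s, b$ are an arbitrary-units scale and a residual flat
background (real capillary subtraction is never perfect).

**Form factor.** The transverse electron-density contrast is modeled as a
symmetric three-Gaussian profile: unit-amplitude headgroup Gaussians at
$\pm z_H$ of width $\sigma_H$, and a chain-region Gaussian of relative
amplitude $\rho_C < 0$ and width $\sigma_C$ at the bilayer center. Its
Fourier transform is analytic:

$$ F(q) = \sqrt{2\pi}\left[2\sigma_H e^{-\sigma_H^2 q^2/2}\cos(q z_H)
        + \rho_C \sigma_C e^{-\sigma_C^2 q^2/2}\right]. $$

The tests verify this expression against direct numerical quadrature of the
real-space profile at 1e-6 relative accuracy. The membrane thickness is the
standard headgroup-Gaussian convention

$$ d_B = 2(z_H + 2\sigma_H), $$

so that, e.g., $z_H = 20.1$ Å, $\sigma_H = 2.5$ Å gives $d_B = 50.2$ Å.

**Structure factor.** Inter-bilayer correlations follow modified Caillé
theory for a stack of $N$ bilayers with repeat $d$ and bending-fluctuation
parameter $\eta$:

$$ S(q) = N + 2\sum_{k=1}^{N-1}(N-k)\cos(kqd)\,
   e^{-(d/2\pi)^2 q^2 \eta\,\gamma_E}\,(\pi k)^{-(d/2\pi)^2 q^2 \eta}, $$

with $\gamma_E$ the Euler–Mascheroni constant. The truncated sum can ring
slightly negative between orders; it is floored at zero before mixing
because it enters the intensity as a weight. Stack-size polydispersity is
not modeled: $N$ is a single integer, fitted exhaustively over a small range
(default 1–8). At $N = 1$, $S \equiv 1$ and the mixture becomes independent
of $N_{UV}$, a degeneracy the tests assert explicitly.

**Fitting.** `fit_curve()` minimizes
$\sum_i [(I_i^{obs} - I_i^{model})/\sigma_i]^2$ with bounded
Levenberg–Marquardt over the nine continuous parameters. The weighted-LS
landscape is multimodal in $d$ (Bragg-peak registration) and has shallow
secondary basins in which $(N_{UV}, s)$ settle slightly biased, so three
devices are combined:

* multi-start over $d \in \{55, 60, 65, 70, 75, 80\}$ Å
  $\times\ N_{UV} \in \{0.3, 0.7\}$, with the intensity scale initialized
  from the median data/model ratio (a weighted projection is fragile when
  the start model's Bragg peaks are misaligned);
* optimizer restarts from each endpoint (re-launching resets the trust
  region and escapes shallow stalls);
* after the per-$N$ multistart, deterministic $\times 0.8/\times 1.2$
  jitters of the profile-shape parameters
  ($\sigma_H, \sigma_C, \rho_C, \eta, N_{UV}$), accepting only improvements,
  repeated until stable. $N$ selection then compares refined optima; ties go
  to the smaller stack.

Standard errors come from the local quadratic approximation at the optimum
(inverse Hessian scaled by the reduced chi-squared); parameters that finish
on a bound are flagged. A `q_min`/`q_max` trim is exposed because beam-stop
contamination at low q is common.

On seeded synthetic curves with 1% multiplicative noise in the
52%-unilamellar regime ($d = 65.8$ Å, $N = 5$, $\eta = 0.1$), median
recovery over 20 curves is well within 2% on $d_B$, 0.05 on $N_{UV}$, and
0.5 Å on $d$; the 87%-unilamellar regime — only 13% of the signal carrying
lamellar correlations — recovers the unilamellar percentage within a few
points. The tests run these exact experiments.

## DSC: transition parameters and the cooperative unit

A thermogram is reduced in four steps. (1) A linear chord through the user's
two anchor temperatures is subtracted and the excess heat capacity outside
the window zeroed — the baseline model is deliberately the simplest one
since nothing in the data motivates more structure. (2) The transition
temperature $T_m$ is the temperature of maximum excess $C_p$, refined by a
parabola through the three samples around the discrete maximum (reported
resolutions of 0.1 °C are finer than plausible raw spacing). (3) The full
width at half maximum $T_{1/2}$ interpolates each half-height crossing
linearly; each crossing is located from both walking directions (identical
on a clean monotone flank, bracketing the true crossing with opposite bias
under noise) and averaged. (4) The calorimetric enthalpy $\Delta H_{cal}$ is
the trapezoidal integral over the window.

The van't Hoff enthalpy uses the conventional approximate two-state
expression

$$ \Delta H_{VH} \simeq \frac{4 R T_m^2}{T_{1/2}}, $$

with $R = 1.9872$ cal mol^-1 K^-1 so the result is in kcal/mol, and the
cooperative unit is $CU = \Delta H_{VH}/\Delta H_{cal}$, reported rounded to
the nearest integer (enthalpies to three significant figures).

Two estimator properties are worth knowing and are asserted by tests rather
than corrected:

* **The factor-4 bias.** For an exact two-state transition the FWHM obeys
  $T_{1/2} = 3.5255\,R T_m^2/\Delta H_{VH}$ (half-maximum at
  $K = 3 \pm 2\sqrt2$), so the factor-4 estimator over-reports a true
  two-state enthalpy by $4/3.5255 \approx 1.134$. The convention is kept
  because it is what the field reports; the synthetic generators therefore
  use *true* enthalpies such that the factor-4 estimate reproduces
  conventional values.
* **Peak-position shift.** The two-state excess heat capacity
  $C_p \propto T^{-2} K/(1+K)^2$ peaks slightly *below* the thermodynamic
  $T_m$ (by $4/(T_m a^2)$ with $a = \Delta H_{VH}/R T_m^2$, about 0.1 K for
  the regimes here). `transition_parameters()` reports the position of the
  measured maximum, which is what a thermogram actually shows.

Under additive scan noise the discrete maximum overshoots the true peak
height, which pulls both half-crossings slightly inward; at the noise level
used for validation this leaves a residual 2–3% high bias in
$\Delta H_{VH}$, smaller than typical replicate scatter and documented here
rather than smoothed away.

Replicate handling (`analyze_replicates()`) runs the full chain per scan and
reports means and sample SDs; CU statistics come from per-scan CU values,
not from a ratio of means. Scans failing analysis (e.g. truncated peaks) are
excluded with a message; the function errors only when no scan survives.

The two-state generator itself is exact: its integral equals
$\Delta H_{cal}$ (the curve is an exact differential of
$\Delta H_{cal}\,\theta$), its height is
$\Delta H_{cal}\Delta H_{VH}/(4RT_m^2)$, and its FWHM is the $3.5255$
expression — the three identities the test suite checks to 0.1–1%. Its grid
must cover $T_m \pm 2$ FWHM (leaving < 0.2% of the enthalpy outside); wider
grids are used where integrals must close tighter. Note that broad
endotherms like the high-dose regimes (FWHM 14–19 K) genuinely cannot be
integrated to 0.1% inside a 50 K instrument window — the synthetic
validation uses wider grids than a real scan would offer.

## Laurdan GP imaging

Laurdan's emission red-shifts with interfacial hydration, so the
generalized polarization

$$ GP = \frac{I_{440} - G\,I_{490}}{I_{440} + G\,I_{490}} $$

is high in ordered, low in disordered phases. The instrument correction
factor $G$ multiplies the red channel (the convention of the standard
calibration procedure) and is obtained from a standard of known GP:
$G = (I_{440}/I_{490})(1 - GP_{ref})/(1 + GP_{ref})$. The reference GP is
always user-supplied — no DMSO-standard value is hardcoded. Pixels whose
corrected total intensity falls below a threshold are masked, never divided.
GP is invariant to any common rescaling of both channels, which the tests
assert exactly.

**Segmentation.** A GUV imaged at its equator (as is standard, to avoid
photoselection) appears as a bright ring. The ring is located from the
intensity-weighted centroid and the radial intensity-profile peak (an error
is raised if the peak does not exceed 3x the background level); an annulus
of configurable width around that radius is the analysis region. Within the
ring, pixels split into l~o~/l~d~ at the midpoint of the two dominant modes
of the GP histogram — a rule that transfers across intensity scales, unlike
a fixed GP cutoff. Frames with an effectively unimodal histogram fall back
to the global median split; the higher-GP class is labeled l~o~ by
convention. Per-frame means and SDs for l~o~, l~d~ and the whole ring are
tabulated by `gp_timeseries()`, with failed frames flagged rather than
fatal.

**Generator.** `simulate_guv_frames()` builds frames by inverting the GP
definition at a chosen total intensity: $I_{440} = S(1+GP)/2$,
$I_{490} = S(1-GP)/(2G)$, then applies per-channel Poisson noise. The
default regime — radius 40 px in a 128 px frame, a 120° l~o~ arc at GP 0.45
against an l~d~ remainder at 0.05, 500 counts per ring pixel, and a +0.05 GP
step in both phases at frame 3 emulating interfacial dehydration upon
compound addition — is the configuration the recovery tests run end to end.
Per-pixel GP shot noise is approximately $1/\sqrt S$, so region means over
hundreds of ring pixels are recovered to well under 0.02 while single
pixels are not.

## Synthetic data: what it does and does not show

All validation inputs are generated, seeded and embedded with their ground
truth. Noise models follow the conventional choice per instrument class:
multiplicative Gaussian for SAXS (relative uncertainty roughly constant
across the measured range), additive Gaussian for DSC, Poisson for
photon-counting images. Noiseless outputs are exactly invertible by the
corresponding analysis operation, and identical seeds give bit-identical
data without disturbing the caller's RNG stream.

The generators emulate idealized versions of the real experiments: a single
vesicle population with one stack size, an exactly two-state endotherm, one
perfectly circular vesicle per frame with piecewise-constant GP. Passing
recovery tests therefore demonstrates the correctness of the estimators
under the stated noise, not robustness to multi-population suspensions,
multi-peak thermograms, non-circular or multiple vesicles, bleaching, or
drift — all explicitly out of scope.

## Problem sizes and defaults

Validation uses 300-point SAXS curves on 0.015–0.447 Å^-1 (a typical
laboratory-source window around the first two lamellar orders) with 20
seeded curves per regime for recovery statistics; DSC grids at 0.01–0.05 K
spacing with 7 replicate scans per condition; 128 px GUV frames with 6-frame
time series and 10 seeded frames for recovery statistics. These sizes make
the estimator statistics stable while keeping the full validation suite
fast on a single CPU.

## Known limitations

* The Caillé stack size is a single fitted integer; real suspensions have
  polydisperse, possibly q-dependent effective stack sizes.
* Instrument resolution smearing is not deconvolved; on smeared data the
  fitted $\eta$ absorbs some of the smearing.
* The factor-4 van't Hoff convention overestimates two-state enthalpies by
  ~13% by construction; cross-study comparisons should use the same
  convention.
* Ring segmentation assumes one dominant vesicle per frame; fields with
  several bright vesicles need prior cropping.
* The two-phase split assumes at most two GP populations on the ring; more
  complex coexistence collapses onto the two dominant modes.
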