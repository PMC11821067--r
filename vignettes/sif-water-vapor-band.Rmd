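---
title: "Retrieving solar-induced fluorescence at the 719 nm water-vapor band: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieving solar-induced fluorescence at the 719 nm water-vapor band}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sifband)
```

## What the package simulates, and why

True canopy fluorescence cannot be measured directly in the field: the
emission overlaps spectrally with reflected sunlight and is two orders of
magnitude weaker. Algorithm evaluation therefore rests on simulation,
where the true `SIF(λ)` is known by construction. `sifband` implements a
self-contained emulator of such a simulation study: canopy reflectance
and fluorescence with controllable biophysical drivers, a parametric
atmosphere whose 719 nm water-vapor band deepens with the water-vapor
column (WVC), an instrument model, seven retrieval algorithms, and the
error metrics and sweeps needed to compare them.

The emulator stands in for a full canopy radiative-transfer and
line-by-line atmospheric simulation. It reproduces the *morphology* that
drives retrieval behavior — line positions and relative depths, red-edge
reflectance shape, two-peak emission, SNR-scaled channel noise — not the
underlying physics. Consequences of that choice are collected under
*Limitations* below.

## The forward model

At-sensor upwelling radiance over a Lambertian canopy is

$$L(\lambda) = \frac{E(\lambda)}{\pi} R(\lambda) + \mathrm{SIF}(\lambda),$$

with `E` the downwelling irradiance (mW m⁻² nm⁻¹), `R` the reflectance
and `SIF` the fluorescence radiance (mW m⁻² nm⁻¹ sr⁻¹). All scenes are
generated on a 0.005 nm native grid over 650–815 nm (the tower
spectrometer range), so that convolution to a 0.3 nm instrument line
shape is resolved by ~60 native samples per FWHM.

### Atmosphere

Transmittance follows Beer–Lambert over small Gaussian optical-depth
line lists: $T(\lambda) = e^{-u\,k(\lambda)}$, where `u` is the WVC in
g cm⁻² for the H2O multiplet (13 lines, 716.6–730.5 nm, main line at
718.9 nm with unit-column optical depth 0.55) and a fixed unit column
for the O2-B (687.0, 688.3 nm) and O2-A (759.8–762.8 nm, deepest at
760.6 nm) lines. Two properties are contractual and tested: H2O line
depth strictly increases with WVC, and O2 depths are independent of WVC
(`|ΔT| < 1e-12`). The weak broad H2O components between 723 and 731 nm
matter: they keep the band identifiable after 3 nm convolution, as the
real 719 nm band (whose absorption spreads over ~716–735 nm) does.
The solar continuum is a smooth Planck envelope at 5800 K scaled so the
zenith-normalized irradiance at 780 nm is 1300 mW m⁻² nm⁻¹ — above the
930 mW m⁻² nm⁻¹ sunny/cloudy threshold used by the tower pipeline, so
clear-sky simulations classify as sunny at any daytime zenith angle.
WVC is accepted in [0.5, 6] g cm⁻², the emulator's calibration range;
exactly 0 is also accepted as the no-absorption reference.

### Canopy

Reflectance is a double-logistic red edge between a red minimum
(`0.025 + 0.085·exp(−Cab/35)`, deepening with chlorophyll) and a NIR
plateau (rising and saturating with LAI, weakly modulated by leaf
structure, water, and dry matter). The two logistic components (centers
708 and 722 nm, widths 7.5 and 10 nm; the upper-shoulder weight shifts
with leaf water) give the red edge the compound curvature real canopies
show, rather than a single ideal sigmoid. Only monotonicity and range
are contractual: deeper red minimum with Cab, higher plateau with LAI,
`R(680) < R(760)`.

Fluorescence is a two-Gaussian red/far-red emission with peaks near 685
and 738 nm (red:far-red amplitude ratio 0.8, σ = 10 and 16.3 nm),
scaled linearly by the quantum yield Fqe and saturating in LAI and Cab.
The far-red σ was set so the shape's 718.9/760.6 nm ratio is ≈ 1.262,
the canonical conversion ratio between the two retrieval bands computed
from simulated emission spectra; `estimate_ratio()` recovers it from any
set of generated spectra, and the tower pipeline uses it to convert
O2-A-referenced retrievals to the water-vapor band. Over the default
324-scene look-up table the far-red peak spans ≈ 0.44–3.0 mW m⁻² nm⁻¹
sr⁻¹.

The default scene grids (Cab ∈ {20,40,60} µg cm⁻², Cdm ∈ {2,10,20},
Cw ∈ {5,10,20}·10⁻³ cm, N ∈ {1,2}, LAI ∈ {1,3,5}, Fqe ∈ {0.01,0.02})
enumerate 324 combinations; crossing with WVC ∈ {1..5} gives 1620
scene–atmosphere pairs. Solar zenith 30°, nadir view.

### Instrument

The line shape is a unit-area Gaussian of given FWHM truncated at ±4σ
(the line-shape family is a convention; only the FWHM is specified by
instrument data sheets). Sampling defaults to FWHM/2. Noise is additive,
zero-mean, per-channel Gaussian with σ = |signal|/SNR — SNR interpreted
as wavelength-local signal-to-σ, which keeps it dimensionless — and is
applied independently to the irradiance and radiance channels, as the
tower instrument measures them through separate fibers. Noise-free runs
use `snr = Inf`.

## Algorithm parameterizations

The FLD-family quotients are evaluated exactly as written (see the
README table); their reference samples are the grid points nearest the
nominal wavelengths, ties toward the shorter wavelength. The per-band,
per-resolution window tables ship in `default_windows()`; for the H2O
band the absorption wavelength shifts with resolution (718.9 nm at
0.3 nm through 719.5 nm at 3 nm) because convolution moves the apparent
line minimum.

Decisions the window/formula tables leave open, and how this package
takes them:

* **iFLD interpolant.** Apparent reflectance `π L/E` is interpolated
  across the line by a cubic smoothing spline over shoulder samples.
  Masked from the shoulder set: the ±2·FWHM core around the line *and*
  any sample whose irradiance falls below 97 % of a linear baseline
  across the region (i.e. samples inside other absorption features).
  The second mask matters at O2-A, where the deep multiplet otherwise
  pulls the spline and corrupts `α_R`; with it, iFLD's noise-free O2-A
  error stays below one percent (the acceptance script recomputes this).
  `α_SIF` uses the canonical emission shape. With fewer than 8 shoulder samples the result is
  flagged `sparse_shoulder`; below 4 it errors.
* **pFLD basis.** Principal components of a reflectance library,
  retained to 99.9 % variance (cappable via `max_components` for noisy
  libraries). In `run_experiment()` the library is the look-up table
  excluding the scene under test (leave-one-out); in `process_tower()`
  it is a subsampled simulated library degraded to the instrument grid —
  training on the day's own apparent reflectances would embed the
  fluorescence in-filling in the basis.
* **SFM degrees.** Reflectance polynomial degree 2 for windows ≤ 8 nm,
  3 for wider; fluorescence degree 1. Chosen for identifiability against
  window width; SIF is reported at the absorption wavelength (the
  centering point of the scaled wavelength variable).
* **SVD.** Training spectra are column-normalized; up to 4 singular
  vectors (capped at matrix rank) each modulated by polynomials up to
  degree 3, plus the fluorescence shape normalized to 1 at the line
  (upward transmittance 1 for tower geometry). Degree 3 — not 1 — is
  needed because with a noise-free training set the matrix is rank one
  and the polynomial alone must carry the red-edge reflectance across
  the 20 nm window; a linear modulation cannot represent it and the
  retrieval degenerates, orders of magnitude away from the few-percent
  behavior this method is known for.
* **DOAS.** Polynomial degree 3 for windows ≤ 8 nm, 5 for wider; the
  fluorescence regressor `h_F(λ)/L(λ)` uses the measured radiance
  (one-pass linearization, no iteration). The regressor is invariant to
  the amplitude of `h_F` because the shape is normalized at the line.

`retrieve_all()` runs all seven with per-algorithm failure isolation: a
broken window or missing basis produces an error row, not an aborted
table.

## The evaluation harness

`run_experiment()` maps a condition grid (band × FWHM × SNR × WVC) over
a scene table: simulate at native resolution, degrade both channels,
retrieve, and score against the instrument-degraded true SIF at the
absorption wavelength. RMSE and RRMSE (= RMSE/mean(truth)·100) follow
the standard definitions; R² is the squared Pearson correlation and the
slope comes from OLS of estimate on truth with intercept (identical to
regression R² in that case). Scenes where an algorithm errors are
excluded pairwise and counted in `n_excluded`. Reports are pure
functions of (scenes, design, seed); noise replicates default to 1 and
the test suite uses up to 10.

Problem sizes were chosen to keep full runs comfortable on one core:
the full 324-scene table for noise-free orderings and WVC sweeps, a
108-scene stratified subset × 10 replicates for the SNR monotonicity
property, and 25–50-scene subsets for smoke tests.

## The tower pipeline

Field systems alternate downwelling and upwelling acquisitions
("sandwich" observation); `sandwich_interpolate()` pairs each radiance
with irradiance linearly interpolated in time between its bracketing
acquisitions (default maximum gap 5 min) and drops unbracketed records.
QC keeps spectra with positive irradiance in the retrieval window,
`E(780)` above a 50 mW m⁻² nm⁻¹ dawn/dusk floor, and solar zenith below
80°. Weather is classified sunny when `E(780)/cos(SZA) > 930` mW m⁻²
nm⁻¹. Retrievals are aggregated to 30-min or daily means of QC-passing
members (`aggregate_sif()`; aggregation conserves the overall weighted
mean to machine precision). The O2-A 3FLD retrieval, converted by the
emission-shape ratio, serves as the reference series; the conversion
slope is estimated zero-intercept by default (ratio semantics), with a
documented `intercept = TRUE` switch.

`simulate_tower_day()` generates a full synthetic day: solar zenith from
latitude/day-of-year, fluorescence tracking incident light, optional
broken-cloud attenuation, and a smooth diurnal WVC drift (default
±0.4 g cm⁻²) so that a day's downwelling spectra span atmospheric
states — without the drift the same-day SVD training matrix is rank one
(all spectra scalar multiples), which flatters SVD unrealistically.

## What the emulator shows — and does not show

Passing tests demonstrate that the implementation reproduces, on
synthetic scenes with known truth, the qualitative behavior that matters
for band and algorithm choice: sFLD's severe overestimation on the red
edge (positive bias on every scene; errors fall as the line deepens with
WVC, as do iFLD's), the three-band accuracy ordering O2-A > H2O > O2-B
for 3FLD/pFLD/SFM/SVD, SFM's overall superiority and the collapse of the
FLD family at 3 nm resolution where SFM and DOAS remain the two most
accurate, and monotone degradation with noise.

They do not demonstrate performance on real spectra. Known limitations:

* Reflectance and emission are smooth by construction. Real canopy
  reflectance carries fine structure; its misfit against the smooth
  models inside DOAS/iFLD is a leading error source in practice. One
  observable consequence: published DOAS errors *decrease* with WVC
  (misfit projection shrinks as the line deepens), while in this
  emulator DOAS's only residual is the log-linearization term, which
  *grows* with absorption depth — so that particular trend is not
  reproduced, and the corresponding assertion in the acceptance suite
  documents the discrepancy rather than hiding it. Adding sharper
  red-edge structure can flip the DOAS trend, but in our experiments it
  simultaneously destroyed the three-band ordering for SFM/SVD, so the
  smooth contract was kept.
* Absolute RRMSE values depend on the emulator's line depths and
  reflectance slopes and should be read as regime indicators (sFLD tens
  of percent, fit methods below a few percent at 0.3 nm), not as
  reproductions of any published table.
* No aerosols, no upward-transmittance path (taken as 1, appropriate
  for tower geometry at the H2O band where atmospheric correction is
  negligible), no instrument dark current, stray light, or wavelength
  shift.
* The O2-band retrievals are performed without atmospheric correction;
  for real tower data at O2-A that simplification biases the reference
  low and is the main caveat on the cross-band comparison.

## Numerical notes

Convolution uses FFT filtering on the uniform native grid with output
centers snapped to grid points; a flat spectrum maps to itself exactly,
and linearity holds to 1e-10. Least-squares fits use QR (`lsfit`) on
wavelength variables centered at the absorption line and scaled by the
half-window, which keeps design matrices well conditioned even at
degree 5. Degenerate inputs error early with named messages: equal
in/out irradiance (no line), nonpositive radiance in a log window,
rank-deficient designs, under-sampled windows. All randomness flows
through explicit seeds; generated spectra are bit-reproducible given
(scene, seed).
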