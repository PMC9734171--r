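---
title: "Methods: simulating heterodyne laser-ultrasound detection and photoacoustic endoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating heterodyne laser-ultrasound detection and photoacoustic endoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paesim)
```

## The physical model

`paesim` simulates an ultrasound sensor that is itself a short fiber laser.
An acoustic pressure `p` strains the laser cavity and modulates its round-trip
optical path length `L_opt` with a coefficient `S_m` (1/Pa):
`dL_opt/dp = S_m * L_opt`. Because the lasing frequency is pinned to the cavity
resonance (`omega0 / c0 * L_opt = 2 pi m`), the path change pulls the lasing
frequency, `d omega0 / dL_opt = -omega0 / L_opt`, and the frequency deviation
integrates into the laser *phase*. For a tone at acoustic frequency `Omega`
the resulting phase modulation is

```
dtheta(t) = p0 * S_m * (omega0 / Omega) * sin(Omega t),
```

so the acoustic response is amplified by the frequency-ratio gain
`G(Omega) = omega0 / Omega` — about `2e7` for a 200 THz optical carrier and
10 MHz ultrasound. The two orthogonal polarization modes of the fiber laser
lase at slightly different frequencies (beat note `omega_b ~ 2 pi * 1.74 GHz`)
and the torsional-radial acoustic deformation drives them with opposite signs,
so the beat carrier at the photodetector carries the *doubled* modulation
`2 dtheta(t)`. The receiver recovers it as the instantaneous phase
`atan2(Q, I)` of the I/Q-demodulated carrier, and
`Theta(Omega) = 2 S_m(Omega) G(Omega)` (rad/Pa) converts phase back to
pressure. The noise floor referred to the input is the noise-equivalent
pressure density `NEPD(Omega) = N_q(Omega) / Theta(Omega)`, where `N_q` is the
quadrature (phase) noise density of the carrier; amplitude noise `N_i` is
rejected by the arctangent.

```{r response}
spec <- sensor_spec()
spec
f <- seq(3e6, 30e6, length.out = 200)
theta <- phase_response_spectrum(spec, 2 * pi * f)
plot(f / 1e6, theta, type = "l", log = "y",
     xlab = "frequency (MHz)", ylab = "Theta (rad/Pa)")
```

## Parameters and defaults

* `L_opt = 5.87e-3` m: a 2 mm grating pair (4 mm physical round trip) at an
  effective index of 1.468. The constructor snaps `omega0` (default
  2 pi × 193 THz, i.e. 1550 nm) to the nearest exact cavity resonance; the
  integer cavity order is implied, never stored.
* `Sm_base = 1e-6` /Pa, the typical magnitude for silica sensors, shaped by a
  single-pole mechanical resonance at `f_res = 22 MHz` with unit
  low-frequency gain and a configurable quality factor (`Q_res = 5` by
  default). The exact resonance shape of a real fiber requires a
  finite-element model; the single-pole stand-in reproduces the qualitative
  spectrum — a resonance peak near 22 MHz plus a second apparent peak at lower
  frequency where the `1/Omega` gain climbs — without claiming its exact
  values, and `Q_res` is deliberately exposed because no measured value is
  available.
* Noise: flat quadrature density `Nq_density = 1.5e-7` rad/sqrt(Hz) in the
  analysis band, optional 1/f excess below a configurable corner (off by
  default), relative intensity noise `Ni_density = 1e-7` /sqrt(Hz) and a
  relaxation-oscillation intensity tone at 1.7 MHz with configurable depth
  (0 by default; 0.1 in the rejection tests).
* Receiver: the physical beat note sits at 1.74 GHz and is downshifted to
  baseband in hardware, so the simulator synthesizes the carrier directly at a
  configurable intermediate frequency (default `f_if = 50 MHz` on a 250 MS/s
  grid) and keeps `omega_b` as metadata. The demodulation low-pass default is
  200 MHz (the receiver's working bandwidth), capped at filter-design time to
  `min(0.95 f_if, 0.45 fs)` because a cut at or above `f_if` would admit the
  `2 f_if` mixing image.

### A numerical-consistency note

The parameter set above is internally consistent but deliberately
parameterized: with `Sm_base = 1e-6` and `G ~ 2e7` the simulated in-band
response is tens of rad/Pa, so the linear (narrowband, `dtheta << pi/6`)
regime corresponds to millipascal-scale pressures and the simulated NEP is
far below a physical hydrophone's. Simulations therefore use mPa-scale
phantom amplitudes, and the calibration-loop demonstrations scale the
reference hydrophone's noise to the same pressure scale (its physical
defaults — 55 mV/MPa, 41 dB, 8000 averages, 768 Pa r.m.s. noise — remain the
`hydrophone_spec()` defaults). All recovery properties (round-trip error, AM
rejection, density recovery, sO2 accuracy) are scale-invariant, so nothing in
the validation depends on this choice.

## Numerical choices

* **Transduction in the frequency domain.** `pressure_to_phase()` scales each
  spectral component by `S_m G` and rotates it by +pi/2 (the quadrature
  relation between a cosine pressure and the sine phase response); DC and the
  Nyquist bin map to zero. `phase_to_pressure()` applies the exact inverse
  inside the analysis band (3–30 MHz by default) and zeroes the rest; the
  pair is exact to machine precision for band-limited periodic signals, and
  edge leakage on cropped records is kept out of measurements by padding
  (`chain_through_sensor()`) or interior windows.
* **Band-limited carrier noise.** Noise is synthesized brick-wall-limited to
  `min(f_if, fs/2 - f_if)`. Discrete white noise extending to Nyquist would
  alias around the carrier: the folded sidebands decorrelate, inflating the
  demodulated density by ~22% and leaking amplitude noise into phase at
  1/sqrt(2) — an artifact of full-band sampling that a physical receiver,
  which band-limits before digitizing, never exhibits. A front-end bandpass
  around `f_if` (`rf_prefilter`) is also applied by default.
* **Filters.** Linear-phase FIR low-passes applied forward–backward
  (zero phase), so photoacoustic arrival times — hence depth maps — are not
  biased; `2 * filter_taps` transient samples are trimmed at each end.
  Residual carrier-frequency offset appears as a phase ramp and is removed by
  a least-squares line fit; `atan2(0, 0)` returns 0 with a warning.
* **Welch estimator.** One-sided, Hanning window, 1400-sample segments with
  512 overlapping samples by default; normalized so the integrated PSD equals
  the trace variance (checked by a Parseval test). The r.m.s. NEP integrates
  `NEPD(f)^2 df` with `f` in ordinary Hz — the only convention under which a
  flat 1.5 mPa/sqrt(Hz) density over 3–30 MHz gives the printed ~8 Pa
  (`sqrt((1.5e-3)^2 * 27e6) = 7.79`).
* **Masking over clipping.** Calibration bins where the reference spectrum
  has no energy are masked (`NA`) rather than divided, and masks propagate
  through `nepd_spectrum()`; `rms_nep()` bridges interior masked bins by
  interpolation with a warning.

## The synthetic phantoms and what they do (not) show

`make_vessel_phantom()` builds a seeded branching tree — trunks crossing the
slab (alternating arterial sO2 0.92–0.98 and venous 0.60–0.72), branches, and
capillaries (0.75–0.85) at depths around 1 mm — emulating the
trunk-plus-branch mucosal vasculature the endoscope images.
`forward_aline()` is a ray-based optical-resolution forward model: a Gaussian
beam (waist FWHM 7.4 um; width growing with defocus over an independent
Rayleigh-range parameter, 119 um by default so that the width is ~20 um at
±300 um) deposits energy where it crosses a vessel, weighted by the
beam-blurred vessel cross-section and by the hemoglobin absorption
`mu_a(lambda) ∝ eps_HbO2(lambda) sO2 + eps_Hb(lambda) (1 - sO2)` at 532/558 nm
(extinction values from a standard tabulated compilation; their absolute
scale cancels in sO2). Each absorber emits a Gaussian-derivative pulse
(30 ns default — the emitted waveform is not otherwise constrained) arriving
after the one-way flight `depth / 1500 m/s` (water coupling), and the two
wavelengths share one record separated by the interleave delay (1500 ns
raster / 2300 ns endoscopic).

The model omits full acoustic wave propagation, acoustic heterogeneity,
optical scattering and spectral coloring with depth. Passing tests therefore
demonstrate that the *detection chain and processing pipeline* are correct
and self-consistent — not that the system would achieve the same numbers in
scattering tissue.

## Design choices made where the design was open

* A-line amplitudes are measured as peak-to-peak values inside an automatic
  gate centered on the envelope peak, with the envelope smoothed over one
  pulse width before peak detection and thresholding. Raw extreme values over
  a full record would be biased upward by noise (defeating the `3 * noise
  RMS` masking rule and compressing the two-wavelength amplitude ratio toward
  sO2 = 0.5).
* Arrival times come from the 532 nm channel when both are present
  (configurable); depth is `arrival * c_sound` (one-way flight).
* Rotational scans trust the configured geometry (2000 A-lines × 0.1° =
  200° sector) rather than any wider nominal coverage; lateral arc step is
  `working_distance * angle_step`, pullback row pitch
  `pullback_speed / bscan_rate`.
* The C_Hb map is the 532 nm peak-to-peak amplitude (configurable to the
  other channel); fluence normalization between wavelengths uses the
  configured pulse-energy ratio (equal by default).
* Segmentation: Otsu's bimodal split with small-object removal (9 px) on
  8-connected components; skeletons by Zhang–Suen thinning; junctions are
  skeleton pixels with ≥3 neighbours; branches shorter than 3 px are dropped;
  branch diameter is `2 * mean(distance transform) - 1` pixels (the distance
  transform reaches the first background pixel center, half a pixel beyond
  the boundary on each side). "Vessel density" is the vessel-pixel fraction
  of the ROI; a per-branch count is also reported.
* Repeated-measures ANOVA and Dunnett contrasts are delegated to `stats::aov`
  and `multcomp` and only smoke-tested — the bespoke deliverables are the
  descriptive per-vessel metrics.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run, per property: round-trip
and AM-rejection records of 8–10 k samples at 250 MS/s; a 2 ms noise record
(500 k samples) for the Welch/NEPD loop; blade-edge scans of 80–100 A-lines
at three focal depths; a 48 × 48 full-chain raster over a three-vessel
phantom at 20 dB SNR plus 32 × 32 scans at three focal offsets for the
depth-invariance check; and two 100 × 100 pressure-domain scans of four- and
five-vessel phantoms for the segmentation/density statistics. These sizes
make every recovery overdetermined while keeping a full run in a few
minutes; all randomness is seeded.

## Known limitations

* The `S_m(Omega)` resonance is a one-pole stand-in; measured response curves
  of a real fiber sensor will differ in detail, so absolute NEPD spectra are
  illustrative, not predictive.
* The forward model is ray-based: no diffraction of the acoustic wave, no
  bandwidth limitation from sensor geometry, no fluence attenuation with
  depth (sO2 depth-invariance in the simulator is therefore a property of
  the processing, not evidence about chromophore-dependent fluence bias).
* Scan conversion of rotational maps is nearest-neighbour and intended for
  display only.
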