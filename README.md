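# paesim

Simulation and processing for optical-resolution photoacoustic endoscopy
built on a heterodyne fiber-laser ultrasound sensor.

## The problem

Optical-resolution photoacoustic endoscopy maps hemoglobin concentration
(C<sub>Hb</sub>), depth and oxygen saturation (sO₂) inside body cavities by
firing interleaved 532/558 nm nanosecond pulses and detecting the
laser-generated ultrasound. When the detector is itself a short fiber laser,
the pressure wave strains the cavity (path modulation coefficient *S*<sub>m</sub>,
∼10⁻⁶ Pa⁻¹ for silica), pulls the lasing frequency through the resonance
condition, and thereby phase-modulates the light with a gain

  *G*(Ω) = ω₀ / Ω

— the ratio of the optical carrier to the acoustic frequency, about 2×10⁷ at
ω₀ = 2π × 200 THz and Ω = 2π × 10 MHz. The two polarization modes beat at
∼1.74 GHz and carry opposite phase shifts ±Δθ(t), so I/Q demodulation of the
beat recovers the doubled modulation 2Δθ(t) through the response

  Θ(Ω) = 2 *S*<sub>m</sub>(Ω) · *G*(Ω)  (rad/Pa),

with noise floor NEPD(Ω) = *N*<sub>q</sub>(Ω) / Θ(Ω) and band-integrated
r.m.s. NEP = √∫ NEPD(f)² df.

`paesim` implements this chain end to end on synthetic inputs, for people who
want to study, test or extend the processing side of such a system without
hardware: sensor transduction and noisy carrier synthesis, I/Q phase
demodulation and pressure reconstruction, hydrophone-referenced calibration
(Welch phase-noise estimation, NEPD, r.m.s. NEP), digital vasculature and
blade-edge phantoms with a dual-wavelength Gaussian-beam forward model,
raster and rotational+pullback scan assembly, linear sO₂ unmixing,
edge-spread resolution estimation, and vessel segmentation /
skeletonization / time-lapse statistics.

## Worked example

Simulate a three-vessel phantom at 20 dB SNR through the full detection chain
(pressure → laser phase → noisy heterodyne carrier → I/Q demodulation →
calibrated pressure → feature maps), then unmix sO₂:

```r
library(paesim)

opt   <- optical_model()                             # 532/558 nm, 7.4 um waist
spec  <- sensor_spec()                               # 193 THz fiber laser sensor
cfg   <- demod_config(f_if = 50e6, lowpass_cut = 40e6)
geom  <- scan_geometry("raster", raster_range = c(6e-4, 6e-4),
                       raster_pixels = c(48, 48))

truth <- c(0.95, 0.60, 0.80)                         # artery / vein / capillary bed
ph    <- make_vessel_phantom(rng_seed = 1)           # or a hand-built phantom
vs    <- Map(function(s, x) vessel_segment(cbind(x, seq(0, 6e-4, length.out = 25),
                                                 1e-3), 3e-5, s),
             truth, c(1.5e-4, 3e-4, 4.5e-4))
ph$vessels <- vs; ph$bounds <- list(x = c(0, 6e-4), y = c(0, 6e-4),
                                    z = c(0.9e-3, 1.1e-3))

pk <- max(abs(forward_aline(ph, c(1.5e-4, 3e-4), opt, focus_depth = 1e-3)$samples))
ft <- simulate_scan(ph, geom, opt, sensor = spec, demod_cfg = cfg,
                    noise_rms = pk / 10, rng_seed = 31, focus_depth = 1e-3)
maps <- assemble_maps(ft, geom, opt)
maps
#> <functional_maps> 48 x 48 px (raster), 25.0% on mask, mean sO2 0.777
```

The printout says a quarter of the field is vessel (three 60 µm vessels across
600 µm) and the mask-mean sO₂ is 0.78 — the mean of the three programmed
saturations is 0.783. Per-vessel means recovered against the rasterized ground
truth come back within ±0.031 of 0.95/0.60/0.80 at this SNR (see
`tests/testthat/test-acceptance.R`). Headline single-line checks:

```r
gain_factor(sensor_spec(omega0 = 2*pi*200e12, snap_resonance = FALSE), 2*pi*10e6)
#> [1] 2e+07
rms_nep(spectral_density(seq(3e6, 30e6, length.out = 2001),
                         rep(1.5e-3, 2001), "Pa Hz^-1/2"), c(3e6, 30e6))
#> [1] 7.794229        # i.e. 8 Pa to the nearest pascal
lateral_step(scan_geometry("rotational")) * 1e6
#> [1] 4.799655        # 5 um to the nearest micrometer
```

A blade-edge scan recovers the configured beam width from the line-spread
function: 7.43 µm at focus for the 7.4 µm waist and 20.1 µm at ±300 µm
defocus (`edge_resolution()`), matching the configured defocus profile
(`beam_fwhm()`).

See `vignettes/heterodyne-pae-methods.Rmd` for the model, its assumptions,
every tunable parameter, and what the synthetic phantoms do and do not
demonstrate. A thin command-line front end with `simulate-scan`,
`process-scan`, `calibrate` and `edge-resolution` subcommands is installed at
`inst/cli/paesim.R`.

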