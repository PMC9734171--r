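# Shared fixtures: all built in code, sized for fast runs.

FS <- 250e6

# noiseless sensor with a flat S_m spectrum (no mechanical resonance)
quiet_flat_spec <- function(...) {
  sensor_spec(f_res = Inf, Nq_density = 0, Ni_density = 0, ...)
}

default_cfg <- function(...) demod_config(f_if = 50e6, lowpass_cut = 40e6, ...)

# single-tone pressure trace: p(t) = -p0 cos(Omega t)
tone_pressure <- function(p0, f, duration = 20e-6, fs = FS) {
  tone_trace(acoustic_tone(p0, 2 * pi * f), fs, duration)
}

# Gaussian-derivative pressure pulse centered at tc
pulse_pressure <- function(amp, tc, duration, fs = FS, fwhm = 30e-9) {
  t <- (0:(round(duration * fs) - 1)) / fs
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  s <- -(t - tc) / sig * exp(-(t - tc)^2 / (2 * sig^2))
  time_trace(amp * s / max(abs(s)), fs, "Pa")
}

# interpolate trace `ref` onto the time grid of trace `x`
resample_onto <- function(ref, x) {
  stats::approx(trace_times(ref), Re(ref$samples), xout = trace_times(x))$y
}

relative_rms_error <- function(x, ref) {
  sqrt(mean((x - ref)^2)) / sqrt(mean(ref^2))
}

# phantom of straight parallel vessels along y at given x positions / sO2
parallel_vessel_phantom <- function(so2s, x_pos, radius = 3e-5, z = 1.0e-3,
                                    extent = 6e-4) {
  vs <- Map(function(s, x) {
    vessel_segment(cbind(x, seq(0, extent, length.out = 25L), z), radius, s)
  }, so2s, x_pos)
  structure(list(kind = "vasculature", vessels = vs, edges = list(),
                 bounds = list(x = c(0, extent), y = c(0, extent),
                               z = c(z - 1e-4, z + 1e-4))),
            class = "phantom")
}

single_point_phantom <- function(x, y, z, so2 = 1, radius = 1e-5) {
  structure(list(kind = "vasculature",
                 vessels = list(vessel_segment(matrix(c(x, y, z), 1), radius, so2)),
                 edges = list(), bounds = NULL),
            class = "phantom")
}

# amplitude profile of a blade-edge scan along x
edge_profile <- function(edge_depth, focus_depth, xs, edge_pos = 2e-4,
                         optical = optical_model()) {
  ph <- make_blade_edge(position = edge_pos, orientation = "x",
                        depth = edge_depth)
  vapply(xs, function(x) {
    tr <- forward_aline(ph, c(x, 0), optical, focus_depth = focus_depth)
    w1 <- demux_wavelengths(tr, optical$pulse_delay)[[1]]
    max(w1$samples) - min(w1$samples)
  }, 0)
}
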