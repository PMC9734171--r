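test_that("gain factor is the optical-to-acoustic frequency ratio", {
  s200 <- sensor_spec(omega0 = 2 * pi * 200e12, snap_resonance = FALSE)
  expect_identical(gain_factor(s200, 2 * pi * 10e6), 2e7)
  expect_equal(gain_factor(s200, s200$omega0), 1)
  s193 <- sensor_spec(omega0 = 2 * pi * 193e12, snap_resonance = FALSE)
  expect_equal(gain_factor(s193, 2 * pi * 25e6), 7.72e6)
  # exact identity G(Omega) * Omega = omega0 across a grid
  Om <- 2 * pi * seq(1e6, 100e6, length.out = 37)
  expect_equal(gain_factor(s193, Om) * Om, rep(s193$omega0, 37))
  expect_error(gain_factor(s193, 0), "positive")
  expect_error(gain_factor(s193, -1), "positive")
})

test_that("sensor spec validates and snaps the cavity resonance condition", {
  spec <- sensor_spec()
  m <- spec$omega0 * spec$L_opt / (2 * pi * 299792458)
  expect_equal(m, round(m), tolerance = 1e-9)
  raw <- sensor_spec(snap_resonance = FALSE)
  expect_equal(spec$omega0 / raw$omega0, 1, tolerance = 1e-4)
  expect_error(sensor_spec(L_opt = -1))
  expect_error(sensor_spec(Nq_density = -1e-9))
})

test_that("S_m spectrum has unit low-frequency limit, Q-fold resonance peak and roll-off", {
  spec <- sensor_spec(Sm_base = 1e-6, f_res = 22e6, Q_res = 5)
  expect_equal(sm_spectrum(spec, 2 * pi * 1), spec$Sm_base, tolerance = 1e-9)
  expect_equal(sm_spectrum(spec, 2 * pi * 22e6), spec$Sm_base * 5)
  # monotone decrease well above resonance
  f_hi <- seq(50e6, 500e6, length.out = 20)
  vals <- sm_spectrum(spec, 2 * pi * f_hi)
  expect_true(all(diff(vals) < 0))
  # flat spectrum variant
  flat <- sensor_spec(f_res = Inf)
  expect_equal(sm_spectrum(flat, 2 * pi * c(1e6, 10e6, 40e6)),
               rep(flat$Sm_base, 3))
})

test_that("phase response equals 2 S_m G and shows a resonance-side peak", {
  spec <- sensor_spec(Q_res = 20)
  Om <- 2 * pi * seq(3e6, 30e6, length.out = 200)
  expect_equal(phase_response_spectrum(spec, Om),
               2 * sm_spectrum(spec, Om) * gain_factor(spec, Om))
  # an interior local maximum near the mechanical resonance
  th <- phase_response_spectrum(spec, Om)
  i_pk <- which.max(th[Om > 2 * pi * 10e6]) + sum(Om <= 2 * pi * 10e6)
  f_pk <- Om[i_pk] / (2 * pi)
  expect_gt(f_pk, 18e6)
  expect_lt(f_pk, 24e6)
  expect_gt(i_pk, 1)
  expect_lt(i_pk, length(Om))
  # decreasing at the low band edge: the gain roll-up dominates there
  expect_lt(th[2], th[1])
})

test_that("pressure-to-phase transduction is the quadrature-shifted Sm*G scaling", {
  flat <- quiet_flat_spec()
  # zero in, zero out
  z <- time_trace(numeric(512), FS, "Pa")
  expect_equal(pressure_to_phase(flat, z)$samples, numeric(512))
  # -p0 cos(Omega t) -> p0 Sm G sin(Omega t)
  f0 <- 10e6
  p <- tone_pressure(1e-3, f0)
  dth <- pressure_to_phase(flat, p)
  expected_amp <- 1e-3 * flat$Sm_base * gain_factor(flat, 2 * pi * f0)
  t <- trace_times(p)
  expect_equal(dth$samples, expected_amp * sin(2 * pi * f0 * t),
               tolerance = 1e-9)
  # doubled variant
  expect_equal(pressure_to_phase(flat, p, doubled = TRUE)$samples,
               2 * dth$samples)
  # linearity
  p3 <- time_trace(3 * p$samples, FS, "Pa")
  expect_equal(pressure_to_phase(flat, p3)$samples, 3 * dth$samples)
  expect_error(pressure_to_phase(flat, time_trace(1, FS, "rad")), "Pa")
})

test_that("beat synthesis is deterministic under seed and a pure tone when silent", {
  flat <- quiet_flat_spec()
  z <- time_trace(numeric(5000), FS, "rad")   # integer number of carrier periods
  car1 <- synthesize_beat(flat, z, f_if = 50e6, rng_seed = 9)
  car2 <- synthesize_beat(flat, z, f_if = 50e6, rng_seed = 9)
  expect_identical(car1$samples, car2$samples)
  car3 <- synthesize_beat(flat, z, f_if = 50e6, rng_seed = 10)
  expect_false(identical(car1$samples, car3$samples))
  # pure tone: all spectral energy in the f_if bin
  X <- Mod(stats::fft(car1$samples))^2
  f <- (seq_along(X) - 1) * FS / length(X)
  i_if <- which.min(abs(f - 50e6))
  expect_gt(X[i_if] / sum(X[f > 0 & f <= FS / 2]), 0.999)
  # Nyquist / band-clearance guards
  expect_error(synthesize_beat(flat, z, f_if = 130e6), "configuration error")
  fast <- time_trace(sin(2 * pi * 45e6 * (0:4999) / FS), FS, "rad")
  expect_error(synthesize_beat(flat, fast, f_if = 40e6), "configuration error")
})

test_that("noise-free carrier phase equals the doubled modulation", {
  flat <- quiet_flat_spec()
  p <- tone_pressure(1e-3, 10e6)
  dth <- pressure_to_phase(flat, p)
  car <- synthesize_beat(flat, dth, f_if = 50e6, rng_seed = 1,
                         include_noise = FALSE)
  ph <- iq_demodulate(car, default_cfg())
  ref <- resample_onto(pressure_to_phase(flat, p, doubled = TRUE), ph)
  expect_lt(relative_rms_error(ph$samples, ref), 0.01)
})
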