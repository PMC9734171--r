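test_that("wavelength demultiplexing splits the interleaved record and re-concatenates", {
  fs <- FS
  delay <- 1.5e-6
  n1 <- round(delay * fs)
  # zero trace -> two zero traces
  z <- time_trace(numeric(2 * n1), fs, "Pa")
  pz <- demux_wavelengths(z, delay)
  expect_equal(pz[[1]]$samples, numeric(n1))
  expect_equal(pz[[2]]$samples, numeric(n1))
  # synthetic two-pulse record: each pulse lands in its own window
  x <- numeric(2 * n1)
  x[100] <- 1; x[n1 + 200] <- -2
  tr <- time_trace(x, fs, "Pa")
  pp <- demux_wavelengths(tr, delay)
  expect_equal(which(pp[[1]]$samples != 0), 100)
  expect_equal(which(pp[[2]]$samples != 0), 200)
  # demux then concatenate is the identity
  expect_equal(c(pp[[1]]$samples, pp[[2]]$samples), x)
  # overlapping windows are refused
  expect_error(demux_wavelengths(tr, delay, window = 2 * delay), "overlap")
})

test_that("feature extraction measures bipolar amplitude, depth and noise masking", {
  fs <- FS
  n <- 400
  t <- (0:(n - 1)) / fs
  a <- 0.5
  t0 <- 0.6e-6
  sig <- 30e-9 / 2.355
  pulse <- -a * (t - t0) / sig * exp(-(t - t0)^2 / (2 * sig^2)) * exp(1) / 2 * 2
  pulse <- a * pulse / max(abs(pulse))          # symmetric bipolar, peak a
  pair <- list(time_trace(pulse, fs, "Pa"), time_trace(0.5 * pulse, fs, "Pa"))
  ft <- extract_features(pair, noise_rms = 1e-6)
  expect_equal(ft$amp_pp[1], 2 * a, tolerance = 1e-6)
  expect_equal(ft$amp_pp[2], a, tolerance = 1e-6)
  expect_equal(ft$depth, 1500 * t0, tolerance = 0.02)
  expect_true(ft$mask)
  # noise-only line is masked at the default k = 3
  withr::with_seed(8, {
    noise <- list(time_trace(rnorm(n, 0, 1e-4), fs, "Pa"),
                  time_trace(rnorm(n, 0, 1e-4), fs, "Pa"))
  })
  ftn <- extract_features(noise, noise_rms = 1e-4)
  expect_false(ftn$mask)
})

test_that("sO2 unmixing solves the two-wavelength extinction system", {
  opt <- optical_model()
  # amplitudes proportional to oxyhemoglobin extinction -> sO2 = 1
  expect_equal(so2_unmix(opt$eps_hbo2[1], opt$eps_hbo2[2], opt)$so2, 1)
  # proportional to deoxyhemoglobin -> sO2 = 0
  expect_equal(so2_unmix(opt$eps_hb[1], opt$eps_hb[2], opt)$so2, 0)
  # a constructed 50/50 mixture
  mix <- 0.5 * opt$eps_hbo2 + 0.5 * opt$eps_hb
  expect_equal(so2_unmix(mix[1], mix[2], opt)$so2, 0.5, tolerance = 1e-6)
  # arbitrary forward mixtures over a grid are recovered exactly
  for (s in seq(0, 1, by = 0.2)) {
    amp <- s * opt$eps_hbo2 + (1 - s) * opt$eps_hb
    expect_equal(so2_unmix(amp[1], amp[2], opt)$so2, s, tolerance = 1e-9)
  }
  # both zero -> masked; equal spectra -> configuration error
  expect_true(is.na(so2_unmix(0, 0, opt)$so2))
  bad <- optical_model(eps_hbo2 = c(1e4, 1e4), eps_hb = c(1e4, 1e4))
  expect_error(so2_unmix(1, 1, bad), "singular")
})

test_that("scan geometry worked examples: arc step, pullback pitch, raster pitch", {
  rot <- scan_geometry("rotational", angle_step = 0.1, alines_per_bscan = 2000,
                       working_distance = 2.75e-3, pullback_speed = 10e-6,
                       bscan_rate = 1)
  expect_equal(lateral_step(rot), 4.80e-6, tolerance = 1e-3)
  expect_equal(round(lateral_step(rot) * 1e6), 5)
  expect_equal(pullback_pitch(rot), 10e-6)
  ras <- scan_geometry("raster", raster_range = c(6e-3, 6e-3),
                       raster_pixels = c(1500, 1500))
  expect_equal(lateral_step(ras), 4e-6)
  expect_error(scan_geometry("rotational", angle_step = 0.2,
                             alines_per_bscan = 2000), "360")
})

test_that("map assembly respects geometry, congruence and the off-mask rule", {
  opt <- optical_model()
  geom <- scan_geometry("rotational", alines_per_bscan = 20)
  poses <- scan_poses(geom, n_bscans = 3)
  expect_equal(attr(poses, "dims"), c(3, 20))
  expect_equal(diff(poses$x[1:2]), lateral_step(geom))
  n <- nrow(poses)
  amp <- s <- rep(0.5, n)
  feats <- data.frame(
    x = poses$x, y = poses$y,
    amp1 = 0.6 * opt$eps_hbo2[1] + 0.4 * opt$eps_hb[1],
    amp2 = 0.6 * opt$eps_hbo2[2] + 0.4 * opt$eps_hb[2],
    arrival_time = 6.67e-7, depth = 1e-3,
    mask = rep(c(TRUE, FALSE), length.out = n)
  )
  attr(feats, "dims") <- attr(poses, "dims")
  maps <- assemble_maps(feats, geom, opt)
  expect_equal(dim(maps$so2), c(3, 20))
  expect_true(all(is.na(maps$so2[!maps$mask])))      # nothing off-mask
  expect_equal(unique(stats::na.omit(as.vector(maps$so2))), 0.6,
               tolerance = 1e-9)
  expect_equal(unique(maps$depth[maps$mask]), 1e-3)
  # mismatched grid is refused
  attr(feats, "dims") <- c(4, 20)
  expect_error(assemble_maps(feats, geom, opt), "grid")
})

test_that("fluence normalization uses the pulse-energy ratio between wavelengths", {
  opt_eq <- optical_model()
  opt_2x <- optical_model(pulse_energy = c(250e-9, 125e-9))
  # amplitudes generated under half energy at the second wavelength
  truth <- 0.7
  amp <- truth * opt_eq$eps_hbo2 + (1 - truth) * opt_eq$eps_hb
  feats <- data.frame(x = 0, y = 0, amp1 = amp[1], amp2 = amp[2] * 0.5,
                      arrival_time = 1e-6, depth = 1.5e-3, mask = TRUE)
  attr(feats, "dims") <- c(1, 1)
  geom <- scan_geometry("raster", raster_pixels = c(1, 1))
  maps <- assemble_maps(feats, geom, opt_2x)
  expect_equal(as.vector(maps$so2), truth, tolerance = 1e-9)
})

test_that("blade-edge pipeline recovers the configured beam width at focus and defocus", {
  opt <- optical_model()
  xs <- seq(1.6e-4, 2.4e-4, by = 1e-6)
  fw <- edge_resolution(xs, edge_profile(1.0e-3, 1.0e-3, xs))
  expect_equal(as.numeric(fw), opt$beam_waist_fwhm, tolerance = 0.05)
  # +300 um defocus
  xs2 <- seq(1.0e-4, 3.0e-4, by = 2e-6)
  fw2 <- edge_resolution(xs2, edge_profile(1.3e-3, 1.0e-3, xs2))
  expect_equal(as.numeric(fw2), beam_fwhm(opt, 3e-4), tolerance = 0.05)
  # flat profile has no edge
  expect_error(edge_resolution(xs, rep(1, length(xs))), "no edge")
})

test_that("simulated scans assemble into maps consistent with the phantom truth", {
  opt <- optical_model()
  phant <- parallel_vessel_phantom(c(0.9, 0.65), c(2e-4, 4e-4))
  geom <- scan_geometry("raster", raster_range = c(6e-4, 6e-4),
                        raster_pixels = c(32, 32))
  ft <- simulate_scan(phant, geom, opt, noise_rms = 1e-5, rng_seed = 2,
                      focus_depth = 1.0e-3)
  maps <- assemble_maps(ft, geom, opt)
  expect_s3_class(maps, "functional_maps")
  xs <- (seq_len(32) - 0.5) * 6e-4 / 32
  rast <- rasterize_phantom(phant, xs, xs)
  expect_gt(dice_coefficient(segment_vessels(maps$chb), rast$mask), 0.85)
  # recovered depth on the vessels matches the phantom depth
  expect_equal(mean(maps$depth[maps$mask & rast$mask]), 1.0e-3,
               tolerance = 0.03)
  # per-vessel sO2 at high SNR
  for (s in c(0.9, 0.65)) {
    sel <- rast$mask & !is.na(rast$so2) & abs(rast$so2 - s) < 1e-9 & maps$mask
    expect_equal(mean(maps$so2[sel], na.rm = TRUE), s, tolerance = 0.03)
  }
})
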