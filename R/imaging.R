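#' Split an interleaved dual-wavelength record
#'
#' The two excitation pulses are fired `delay` apart and share one acquisition
#' record; each wavelength owns a window of `window` seconds starting at its
#' firing time. Splitting puts both windows on a common depth axis (both start
#' at t = 0 relative to their own pulse). The acoustic window must not exceed
#' the interleave delay, otherwise the second wavelength's echoes overlap the
#' first window.
#'
#' @param trace a [time_trace()] in Pa holding both responses.
#' @param delay interleave delay (s).
#' @param window acoustic window per wavelength (s, default `delay`).
#' @return A list of two [time_trace()]s, one per wavelength.
#' @export
demux_wavelengths <- function(trace, delay, window = delay) {
  stopifnot(inherits(trace, "time_trace"))
  if (window > delay)
    stop("acoustic window exceeds the interleave delay: wavelength windows overlap")
  fs <- trace$sample_rate
  n1 <- round(delay * fs)
  nw <- round(window * fs)
  n <- length(trace$samples)
  if (n1 < 1L || n1 >= n) stop("delay outside the record")
  if (n1 + nw > n) nw <- n - n1
  tr1 <- time_trace(trace$samples[seq_len(min(nw, n1))], fs, trace$unit, 0)
  tr2 <- time_trace(trace$samples[n1 + seq_len(nw)], fs, trace$unit, 0)
  list(tr1, tr2)
}

#' Per-A-line features: amplitude, arrival time, depth
#'
#' Extracts the peak-to-peak photoacoustic amplitude of each wavelength within
#' the signal gate, the arrival time as the envelope-peak time (magnitude of
#' the analytic signal, smoothed over roughly a pulse width so white noise
#' does not masquerade as a peak) of the preferred channel (the 532 nm channel
#' by default when both are above threshold, else the stronger one), and the
#' depth `arrival_time * c_sound`. A-lines whose smoothed envelope peak stays
#' below `k * noise_rms` on both channels are flagged off-mask.
#'
#' @param pair list of two [time_trace()]s from [demux_wavelengths()].
#' @param c_sound speed of sound (m/s).
#' @param noise_rms noise floor (Pa r.m.s.); `NULL` estimates it from the
#'   median absolute deviation of the first channel.
#' @param k threshold factor (mask if envelope peak < `k * noise_rms`).
#' @param gate optional length-2 time gate (s) within which features are
#'   measured.
#' @param gate_halfwidth optional half-width (s) of an automatic gate centered
#'   on the envelope peak of the reference channel; limits the stretch of
#'   noise-only samples entering the peak-to-peak measurement. Ignored when
#'   `gate` is given.
#' @param prefer_channel channel used for arrival time when both are present
#'   (1 = first wavelength).
#' @param smooth_width envelope smoothing window (s) for peak detection and
#'   thresholding (default 30 ns, about one pulse width).
#' @return A list of class `aline_features` with `amp_pp` (length 2, Pa),
#'   `arrival_time` (s), `depth` (m) and `mask` (logical, TRUE = signal).
#' @export
extract_features <- function(pair, c_sound = .c_sound_default,
                             noise_rms = NULL, k = 3, gate = NULL,
                             gate_halfwidth = NULL, prefer_channel = 1L,
                             smooth_width = 30e-9) {
  stopifnot(length(pair) == 2L, inherits(pair[[1]], "time_trace"))
  fs <- pair[[1]]$sample_rate
  if (is.null(noise_rms))
    noise_rms <- stats::mad(Re(pair[[1]]$samples), center = 0)
  nsm <- max(1L, round(smooth_width * fs))
  smooth <- function(tr) {
    if (nsm <= 1L) return(tr)
    kern <- rep(1 / nsm, nsm)
    y <- stats::filter(tr$samples, kern, sides = 2)
    y[is.na(y)] <- 0
    time_trace(as.numeric(y), tr$sample_rate, tr$unit, tr$t0)
  }
  env_full <- lapply(pair, function(tr) smooth(trace_envelope(tr)))
  peak <- vapply(env_full, function(e) max(e$samples), 0)
  masked <- all(peak < k * noise_rms)
  ch <- if (peak[prefer_channel] >= k * noise_rms) prefer_channel else which.max(peak)
  i_pk <- which.max(env_full[[ch]]$samples)
  arrival <- trace_times(env_full[[ch]])[i_pk]
  if (is.null(gate) && !is.null(gate_halfwidth) && !masked)
    gate <- c(arrival - gate_halfwidth, arrival + gate_halfwidth)
  sub <- lapply(pair, function(tr) {
    if (is.null(gate)) tr else trace_crop(tr, gate[1], gate[2])
  })
  amp_pp <- vapply(sub, function(tr) {
    x <- Re(tr$samples); max(x) - min(x)
  }, 0)
  structure(list(amp_pp = amp_pp, arrival_time = arrival,
                 depth = arrival * c_sound, mask = !masked),
            class = "aline_features")
}

#' Dual-wavelength linear sO2 unmixing
#'
#' Solves the 2 x 2 linear system
#' `amp(lambda_i) = k * (eps_hbo2(lambda_i) * C_HbO2 + eps_hb(lambda_i) * C_Hb)`
#' for the oxy- and deoxyhemoglobin concentrations (fluence-normalized
#' amplitudes assumed); returns `so2 = C_HbO2 / (C_HbO2 + C_Hb)` clipped to
#' `[0, 1]` and the total concentration surrogate `c_hb`. Negative
#' least-squares concentrations are clipped at zero before forming the ratio.
#' Vectorized over amplitude pairs; pairs with both amplitudes zero come back
#' `NA` (masked).
#'
#' @param amp1,amp2 photoacoustic amplitudes at the first and second
#'   wavelength (same units, fluence-normalized).
#' @param optical an [optical_model()] carrying the extinction coefficients.
#' @return A list with numeric vectors `so2` and `c_hb`.
#' @export
so2_unmix <- function(amp1, amp2, optical) {
  stopifnot(length(amp1) == length(amp2), all(amp1 >= 0, na.rm = TRUE),
            all(amp2 >= 0, na.rm = TRUE))
  E <- rbind(c(optical$eps_hbo2[1], optical$eps_hb[1]),
             c(optical$eps_hbo2[2], optical$eps_hb[2]))
  if (abs(det(E)) < 1e-9 * prod(colSums(abs(E)) / 2))
    stop("configuration error: extinction matrix is singular (equal spectra)")
  Einv <- solve(E)
  C1 <- Einv[1, 1] * amp1 + Einv[1, 2] * amp2
  C2 <- Einv[2, 1] * amp1 + Einv[2, 2] * amp2
  C1 <- pmax(C1, 0); C2 <- pmax(C2, 0)
  tot <- C1 + C2
  so2 <- ifelse(tot > 0, pmin(pmax(C1 / tot, 0), 1), NA_real_)
  both_zero <- amp1 == 0 & amp2 == 0
  so2[both_zero] <- NA_real_
  tot[both_zero] <- NA_real_
  list(so2 = so2, c_hb = tot)
}

#' Probe poses of a scan
#'
#' Expands a [scan_geometry()] into the ordered lateral poses of every A-line.
#' Raster grids are row-major with the origin at the scan start; rotational
#' scans are unrolled to arc length at the focal plane (columns) versus
#' pullback position (rows).
#'
#' @param geometry a [scan_geometry()].
#' @param n_bscans number of B-scans (rows) for rotational mode.
#' @param origin length-2 offset (m) added to all poses.
#' @return A data.frame with columns `x`, `y` in scan order and attribute
#'   `dims = c(nrow, ncol)` of the map grid.
#' @export
scan_poses <- function(geometry, n_bscans = 1L, origin = c(0, 0)) {
  if (geometry$mode == "raster") {
    nx <- geometry$raster_pixels[1]; ny <- geometry$raster_pixels[2]
    xs <- origin[1] + (seq_len(nx) - 0.5) * geometry$raster_range[1] / nx
    ys <- origin[2] + (seq_len(ny) - 0.5) * geometry$raster_range[2] / ny
    df <- data.frame(x = rep(xs, times = ny), y = rep(ys, each = nx))
    attr(df, "dims") <- c(ny, nx)
  } else {
    nx <- geometry$alines_per_bscan
    xs <- origin[1] + (seq_len(nx) - 1L) * lateral_step(geometry)
    ys <- origin[2] + (seq_len(n_bscans) - 1L) * pullback_pitch(geometry)
    df <- data.frame(x = rep(xs, times = n_bscans), y = rep(ys, each = nx))
    attr(df, "dims") <- c(n_bscans, nx)
  }
  df
}

#' Functional map set
#'
#' @param chb_map,depth_map,so2_map,mask congruent matrices: hemoglobin
#'   amplitude (arbitrary units), depth (m), oxygen saturation (fraction, NA
#'   off-mask) and the signal-present mask.
#' @param geometry the [scan_geometry()] the maps were assembled under.
#' @return An object of class `functional_maps`.
#' @export
functional_maps <- function(chb_map, depth_map, so2_map, mask, geometry) {
  dims <- dim(chb_map)
  stopifnot(identical(dim(depth_map), dims), identical(dim(so2_map), dims),
            identical(dim(mask), dims))
  if (any(!is.na(so2_map) & !mask))
    stop("so2 values present off-mask")
  rng <- range(so2_map[mask], na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    stop("so2 outside [0, 1] on the mask")
  structure(list(chb = chb_map, depth = depth_map, so2 = so2_map,
                 mask = mask, geometry = geometry),
            class = "functional_maps")
}

#' @export
print.functional_maps <- function(x, ...) {
  cat(sprintf(
    "<functional_maps> %d x %d px (%s), %.1f%% on mask, mean sO2 %.3f\n",
    nrow(x$chb), ncol(x$chb), x$geometry$mode, 100 * mean(x$mask),
    mean(x$so2[x$mask], na.rm = TRUE)))
  invisible(x)
}

#' Assemble per-A-line features into functional maps
#'
#' Places per-A-line features onto the scan grid (row-major in scan order:
#' raster rows, or pullback position x angle for rotational scans), unmixes
#' sO2 from the fluence-normalized wavelength amplitudes on masked-in pixels,
#' and returns the hemoglobin-concentration, depth and sO2 maps. The
#' concentration surrogate defaults to the first-wavelength (532 nm)
#' peak-to-peak amplitude.
#'
#' @param features data.frame with columns `amp1`, `amp2`, `arrival_time`,
#'   `depth`, `mask`, one row per A-line in scan order (as produced by
#'   [simulate_scan()]).
#' @param geometry the [scan_geometry()].
#' @param optical an [optical_model()]; its `pulse_energy` ratio provides the
#'   fluence normalization between wavelengths.
#' @param dims grid dimensions `c(nrow, ncol)`; defaults to the `dims`
#'   attribute of `features`.
#' @param chb_channel channel used for the C_Hb map (1 = 532 nm default).
#' @return A [functional_maps()] object.
#' @export
assemble_maps <- function(features, geometry, optical,
                          dims = attr(features, "dims"), chb_channel = 1L) {
  if (is.null(dims)) stop("grid dimensions unavailable: supply dims")
  if (nrow(features) != prod(dims))
    stop("feature count does not match the scan geometry grid")
  shape <- function(v) matrix(v, nrow = dims[1], ncol = dims[2], byrow = TRUE)
  e_ratio <- optical$pulse_energy[1] / optical$pulse_energy[2]
  amp1 <- features$amp1
  amp2 <- features$amp2 * e_ratio
  mask <- features$mask
  um <- so2_unmix(ifelse(mask, amp1, 0), ifelse(mask, amp2, 0), optical)
  so2 <- ifelse(mask, um$so2, NA_real_)
  chb <- if (chb_channel == 1L) amp1 else amp2
  depth <- ifelse(mask, features$depth, NA_real_)
  functional_maps(shape(chb), shape(depth), shape(so2), shape(mask), geometry)
}

#' Simulate a scan over a phantom
#'
#' Runs the forward model at every pose of the scan geometry and extracts
#' per-A-line features. With `sensor` and `demod_cfg` supplied, each pressure
#' A-line additionally traverses the full detection chain -- phase
#' transduction, noisy heterodyne carrier, I/Q demodulation and calibrated
#' pressure reconstruction -- before feature extraction; otherwise features
#' come from the acoustic pressure directly.
#'
#' @param phantom a `phantom`.
#' @param geometry a [scan_geometry()].
#' @param optical an [optical_model()].
#' @param n_bscans rotational rows (see [scan_poses()]).
#' @param origin scan origin offset (m).
#' @param sensor optional [sensor_spec()] for the full detection chain.
#' @param demod_cfg optional [demod_config()] (required with `sensor`).
#' @param noise_rms additive acoustic noise per A-line (Pa r.m.s.).
#' @param rng_seed base seed; A-line `i` uses `rng_seed + i`.
#' @param reconstruction_band band (Hz) for [phase_to_pressure()] in the full
#'   chain (the 3-30 MHz analysis band by default).
#' @param gate_halfwidth automatic signal-gate half-width (s) for
#'   [extract_features()]; defaults to eight pulse widths.
#' @param threshold_k mask threshold factor for [extract_features()].
#' @param noise_floor noise floor handed to [extract_features()]; `NULL`
#'   derives it from `noise_rms` (or the data when that is 0).
#' @param ... further arguments to [forward_aline()] (e.g. `focus_depth`,
#'   `focus_offset`, `amp_scale`, `sample_rate`, `c_sound`).
#' @return A data.frame (one row per A-line, scan order) with columns `x`,
#'   `y`, `amp1`, `amp2`, `arrival_time`, `depth`, `mask` and attribute
#'   `dims`; feed to [assemble_maps()].
#' @export
simulate_scan <- function(phantom, geometry, optical, n_bscans = 1L,
                          origin = c(0, 0), sensor = NULL, demod_cfg = NULL,
                          noise_rms = 0, rng_seed = 1L,
                          reconstruction_band = c(3e6, 30e6),
                          gate_halfwidth = 8 * optical$pulse_fwhm,
                          threshold_k = 3, noise_floor = NULL, ...) {
  poses <- scan_poses(geometry, n_bscans = n_bscans, origin = origin)
  if (!is.null(sensor) && is.null(demod_cfg))
    stop("supply a demod_config together with the sensor spec")
  c_sound <- list(...)$c_sound
  if (is.null(c_sound)) c_sound <- .c_sound_default
  rows <- vector("list", nrow(poses))
  for (i in seq_len(nrow(poses))) {
    p <- forward_aline(phantom, c(poses$x[i], poses$y[i]), optical,
                       noise_rms = noise_rms, rng_seed = rng_seed + i, ...)
    if (!is.null(sensor)) {
      p <- chain_through_sensor(p, sensor, demod_cfg,
                                rng_seed = rng_seed + i,
                                band = reconstruction_band)
    }
    pair <- demux_wavelengths(p, optical$pulse_delay)
    nf <- noise_floor
    if (is.null(nf)) nf <- if (noise_rms > 0) noise_rms else NULL
    ft <- extract_features(pair, c_sound = c_sound, noise_rms = nf,
                           k = threshold_k, gate_halfwidth = gate_halfwidth)
    rows[[i]] <- data.frame(x = poses$x[i], y = poses$y[i],
                            amp1 = ft$amp_pp[1], amp2 = ft$amp_pp[2],
                            arrival_time = ft$arrival_time,
                            depth = ft$depth, mask = ft$mask)
  }
  out <- do.call(rbind, rows)
  attr(out, "dims") <- attr(poses, "dims")
  out
}

#' Pass a pressure record through the full detection chain
#'
#' Pads the record (so the demodulation filter transient does not eat signal),
#' transduces it to laser phase, synthesizes the noisy heterodyne carrier,
#' I/Q-demodulates and reconstructs calibrated pressure. The returned trace is
#' cropped back to the original window.
#'
#' @param p a [time_trace()] in Pa.
#' @param sensor a [sensor_spec()].
#' @param cfg a [demod_config()].
#' @param rng_seed seed for the carrier noise.
#' @param band reconstruction band (Hz).
#' @return A [time_trace()] in Pa aligned with the input.
#' @export
chain_through_sensor <- function(p, sensor, cfg, rng_seed = NULL,
                                 band = c(3e6, 30e6)) {
  pad <- 2L * cfg$filter_taps + 8L
  x <- c(numeric(pad), Re(p$samples), numeric(pad))
  p_pad <- time_trace(x, p$sample_rate, "Pa", p$t0 - pad / p$sample_rate)
  dth <- pressure_to_phase(sensor, p_pad)
  car <- synthesize_beat(sensor, dth, f_if = cfg$f_if, rng_seed = rng_seed)
  ph <- iq_demodulate(car, cfg)
  pr <- phase_to_pressure(ph, sensor, analysis_band = band)
  ## iq_demodulate trims 2*filter_taps at each end of the padded record
  off <- round((p$t0 - pr$t0) * p$sample_rate)
  keep <- off + seq_along(p$samples)
  keep <- keep[keep >= 1 & keep <= length(pr$samples)]
  time_trace(pr$samples[keep], p$sample_rate, "Pa", p$t0)
}

#' Lateral resolution from a blade-edge profile
#'
#' Fits the edge-spread function of an amplitude profile across a blade edge:
#' the profile is differentiated to the line-spread function and a Gaussian is
#' fitted by nonlinear least squares; the FWHM of that Gaussian is the lateral
#' resolution. Errors out when no edge is present (the profile swing does not
#' dominate its residual fluctuation).
#'
#' @param position lateral coordinates (m), ordered or not.
#' @param amplitude photoacoustic amplitudes at those positions.
#' @return FWHM in m, with the fitted model in attribute `"fit"`.
#' @export
edge_resolution <- function(position, amplitude) {
  stopifnot(length(position) == length(amplitude), length(position) >= 8L)
  o <- order(position)
  x <- position[o]; a <- amplitude[o]
  swing <- max(a) - min(a)
  if (swing <= 0) stop("no edge detected: flat amplitude profile")
  xm <- (x[-1] + x[-length(x)]) / 2
  lsf <- diff(a) / diff(x)
  pk <- max(abs(lsf))
  noise <- stats::mad(lsf, center = 0)
  if (pk < 5 * noise || pk <= 0)
    stop("no edge detected in the amplitude profile")
  sgn <- sign(lsf[which.max(abs(lsf))])
  y <- sgn * lsf
  mu0 <- xm[which.max(y)]
  sigma0 <- max(sum(y > max(y) / 2) * stats::median(diff(x)) / 2.355,
                stats::median(diff(x)) / 2)
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-(xm - mu)^2 / (2 * sigma^2)),
    start = list(A = max(y), mu = mu0, sigma = sigma0),
    lower = c(A = 0, mu = min(x), sigma = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  fwhm <- 2 * sqrt(2 * log(2)) * abs(stats::coef(fit)[["sigma"]])
  structure(fwhm, fit = fit)
}

#' Polar-to-Cartesian scan conversion of a rotational map
#'
#' Nearest-neighbour display conversion of an (angle x pullback) map onto a
#' Cartesian grid around the probe axis at the working distance.
#'
#' @param map matrix (rows = pullback, cols = angle).
#' @param geometry the rotational [scan_geometry()].
#' @param n_px output grid size per side.
#' @return An `n_px` x `n_px` matrix (NA outside the imaged sector).
#' @export
scan_convert <- function(map, geometry, n_px = 400L) {
  stopifnot(geometry$mode == "rotational")
  r <- geometry$working_distance
  ang_span <- (ncol(map) - 1L) * geometry$angle_step * pi / 180
  xs <- seq(-r, r, length.out = n_px)
  out <- matrix(NA_real_, n_px, n_px)
  gx <- matrix(xs, n_px, n_px, byrow = TRUE)
  gy <- matrix(xs, n_px, n_px)
  theta <- atan2(gy, gx)
  theta[theta < 0] <- theta[theta < 0] + 2 * pi
  rad <- sqrt(gx^2 + gy^2)
  ring <- abs(rad - r) <= r / 20
  ai <- round(theta / (geometry$angle_step * pi / 180)) + 1L
  ok <- ring & theta <= ang_span & ai >= 1L & ai <= ncol(map)
  ## display conversion collapses pullback rows: use the first row
  out[ok] <- map[1L, ai[ok]]
  out
}
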