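#' Reference needle-hydrophone specification
#'
#' Parameters of the calibrated reference hydrophone used to measure the
#' pressure spectrum `P(Omega)` against which the sensor phase spectrum
#' `D(Omega)` is ratioed. The hydrophone response is taken flat at `Sn` over
#' the calibration band; its signals are amplified by `gain_db` and pulse time
#' traces are averaged `n_averages` times to reach an adequate SNR.
#'
#' @param Sn hydrophone sensitivity (V/Pa; default 55e-9, i.e. 55 mV/MPa).
#' @param gain_db amplifier gain in dB (default 41).
#' @param n_averages number of pulse-trace averages (default 8000).
#' @param noise_rms hydrophone noise-equivalent pressure, r.m.s. over its band
#'   (Pa; default 768).
#' @return An object of class `hydrophone_spec`.
#' @export
hydrophone_spec <- function(Sn = 55e-9, gain_db = 41, n_averages = 8000,
                            noise_rms = 768) {
  stopifnot(Sn > 0, n_averages >= 1, noise_rms >= 0)
  structure(list(Sn = Sn, gain_db = gain_db,
                 n_averages = as.integer(n_averages), noise_rms = noise_rms),
            class = "hydrophone_spec")
}

#' @export
print.hydrophone_spec <- function(x, ...) {
  cat(sprintf(
    "<hydrophone_spec> Sn = %.3g mV/MPa, gain %.3g dB, %d averages, NEP %.3g Pa\n",
    x$Sn * 1e9, x$gain_db, x$n_averages, x$noise_rms))
  invisible(x)
}

#' Simulate an (averaged) hydrophone voltage record
#'
#' Converts a pressure trace to the amplified hydrophone voltage
#' `v = p * Sn * 10^(gain_db/20)` and adds white voltage noise equivalent to
#' `noise_rms` Pa, scaled down by `sqrt(n_averages)` as coherent pulse
#' averaging would achieve.
#'
#' @param p a [time_trace()] in Pa.
#' @param hspec a [hydrophone_spec()].
#' @param n_averages number of averages (defaults to `hspec$n_averages`).
#' @param rng_seed integer seed; `NULL` uses the current stream.
#' @return A [time_trace()] in V.
#' @export
simulate_hydrophone <- function(p, hspec, n_averages = hspec$n_averages,
                                rng_seed = NULL) {
  stopifnot(inherits(p, "time_trace"), p$unit == "Pa", n_averages >= 1)
  g <- hspec$Sn * 10^(hspec$gain_db / 20)
  sd_v <- hspec$noise_rms * g / sqrt(n_averages)
  with_seed_or_current(rng_seed, {
    v <- Re(p$samples) * g + stats::rnorm(length(p$samples), 0, sd_v)
    time_trace(v, p$sample_rate, "V", p$t0)
  })
}

#' Calibrated acoustic response spectrum D(Omega)/P(Omega)
#'
#' Fourier transforms the sensor phase record `d(t)` and the simultaneously
#' acquired hydrophone record of the same pulse, converts the hydrophone
#' voltage to pressure via `Sn` and the amplifier gain, and returns the
#' magnitude ratio `|D(Omega)| / |P(Omega)|` (rad/Pa) on the common frequency
#' grid within the requested band. Bins where the reference spectrum falls
#' below `floor_frac` of its in-band maximum are masked (`NA`) rather than
#' divided, to avoid fabricating response values from noise.
#'
#' @param sensor_phase [time_trace()] in rad (the doubled heterodyne
#'   modulation, i.e. the quantity [iq_demodulate()] returns).
#' @param hydro_voltage [time_trace()] in V covering the same pulse with the
#'   same sample rate and length.
#' @param hspec a [hydrophone_spec()].
#' @param band analysis band in Hz (default 3-30 MHz).
#' @param floor_frac masking threshold relative to the in-band reference peak.
#' @return A [spectral_density()] with unit `"rad/Pa"` (masked bins `NA`).
#' @export
response_spectrum <- function(sensor_phase, hydro_voltage, hspec,
                              band = c(3e6, 30e6), floor_frac = 1e-3) {
  stopifnot(inherits(sensor_phase, "time_trace"),
            inherits(hydro_voltage, "time_trace"))
  if (sensor_phase$unit != "rad") stop("sensor_phase must be in rad")
  if (hydro_voltage$unit != "V") stop("hydro_voltage must be in V")
  n <- length(sensor_phase$samples)
  if (length(hydro_voltage$samples) != n ||
      sensor_phase$sample_rate != hydro_voltage$sample_rate)
    stop("the two records must share duration and sample rate")
  fs <- sensor_phase$sample_rate
  g <- hspec$Sn * 10^(hspec$gain_db / 20)
  D <- Mod(stats::fft(Re(sensor_phase$samples)))
  P <- Mod(stats::fft(Re(hydro_voltage$samples) / g))
  half <- seq_len(floor(n / 2) + 1L)
  f <- (half - 1L) * fs / n
  inb <- f >= band[1] & f <= band[2]
  f <- f[inb]; D <- D[half][inb]; P <- P[half][inb]
  if (!length(f)) stop("no frequency bins inside the requested band")
  ratio <- D / P
  ratio[P < floor_frac * max(P)] <- NA_real_
  spectral_density(f, ratio, "rad/Pa")
}

## One-sided Welch power spectral density, windowed overlapping segments.
## Normalization: psd_k = 2 |X_k|^2 / (fs * sum(w^2)) (DC/Nyquist undoubled),
## averaged over segments, so that sum(psd) * df ~= mean(x^2).
welch_psd <- function(x, fs, nperseg, noverlap, window = "hanning") {
  n <- length(x)
  if (n < nperseg) stop("trace shorter than one Welch segment")
  w <- switch(window,
              hanning = signal::hanning(nperseg),
              hamming = signal::hamming(nperseg),
              boxcar = rep(1, nperseg),
              stop("unknown window: ", window))
  step <- nperseg - noverlap
  if (step < 1L) stop("noverlap must be smaller than nperseg")
  starts <- seq(1L, n - nperseg + 1L, by = step)
  W <- sum(w^2)
  half <- seq_len(floor(nperseg / 2) + 1L)
  acc <- numeric(length(half))
  for (s in starts) {
    X <- stats::fft(x[s:(s + nperseg - 1L)] * w)
    acc <- acc + Mod(X[half])^2
  }
  psd <- 2 * acc / (length(starts) * fs * W)
  psd[1] <- psd[1] / 2
  if (nperseg %% 2 == 0) psd[length(psd)] <- psd[length(psd)] / 2
  list(freqs = (half - 1L) * fs / nperseg, psd = psd)
}

#' Phase-noise amplitude density by Welch's method
#'
#' Estimates the one-sided phase-noise power spectral density of a signal-free
#' phase record with Welch's averaged-periodogram method (defaults exactly as
#' used for the sensor characterization: 1400-sample segments, Hanning window,
#' 512 overlapping samples) and returns its square root, the amplitude density
#' `N_q(Omega)` in rad/sqrt(Hz).
#'
#' @param nq_trace a [time_trace()] in rad, at least one segment long.
#' @param nperseg segment length in samples.
#' @param noverlap overlapping samples between segments.
#' @param window window name (`"hanning"`, `"hamming"`, `"boxcar"`).
#' @return A [spectral_density()] with unit `"rad Hz^-1/2"`.
#' @export
welch_phase_noise <- function(nq_trace, nperseg = 1400L, noverlap = 512L,
                              window = "hanning") {
  stopifnot(inherits(nq_trace, "time_trace"))
  if (nq_trace$unit != "rad") stop("welch_phase_noise expects a phase trace")
  est <- welch_psd(Re(nq_trace$samples), nq_trace$sample_rate,
                   nperseg, noverlap, window)
  sd <- spectral_density(est$freqs[-1], sqrt(est$psd[-1]), "rad Hz^-1/2")
  attr(sd, "psd_dc") <- est$psd[1]
  sd
}

#' Noise-equivalent pressure density spectrum
#'
#' Pointwise division `NEPD(Omega) = N_q(Omega) / Theta(Omega)`: the phase
#' noise floor referred to the input through the calibrated phase response.
#' The response is interpolated onto the noise grid; bins where the response is
#' masked (or outside its grid) stay masked.
#'
#' @param noise a [spectral_density()] in rad/sqrt(Hz) (from
#'   [welch_phase_noise()]).
#' @param theta a [spectral_density()] in rad/Pa (from [response_spectrum()]
#'   or evaluated from [phase_response_spectrum()]).
#' @return An object of class `nepd_spectrum` with fields `freqs` (Hz), `nepd`
#'   (Pa/sqrt(Hz), `NA` where masked) and `band` (Hz range of valid overlap).
#' @export
nepd_spectrum <- function(noise, theta) {
  stopifnot(inherits(noise, "spectral_density"),
            inherits(theta, "spectral_density"))
  ok <- !is.na(theta$values)
  if (sum(ok) < 2L) stop("response spectrum has fewer than two unmasked bins")
  th <- stats::approx(theta$freqs[ok], theta$values[ok], xout = noise$freqs,
                      rule = 1)$y
  ## propagate the mask: any bin adjacent to a masked response bin stays masked
  masked_frac <- stats::approx(theta$freqs, as.numeric(!ok),
                               xout = noise$freqs, rule = 1)$y
  th[!is.na(masked_frac) & masked_frac > 0] <- NA_real_
  nepd <- noise$values / th
  valid <- which(!is.na(nepd))
  if (!length(valid)) stop("empty overlap between noise and response grids")
  structure(list(freqs = noise$freqs, nepd = nepd,
                 band = range(noise$freqs[valid])),
            class = "nepd_spectrum")
}

#' @export
print.nepd_spectrum <- function(x, ...) {
  inb <- x$freqs >= x$band[1] & x$freqs <= x$band[2]
  cat(sprintf(
    "<nepd_spectrum> %d bins, valid band %.3g-%.3g MHz, median %.3g mPa Hz^-1/2\n",
    length(x$freqs), x$band[1] / 1e6, x$band[2] / 1e6,
    stats::median(x$nepd[inb], na.rm = TRUE) * 1e3))
  invisible(x)
}

#' Band-integrated r.m.s. noise-equivalent pressure
#'
#' `sqrt(integral over the band of NEPD(f)^2 df)` by trapezoidal integration,
#' with the frequency variable in ordinary Hz (the convention under which a
#' flat 1.5 mPa/sqrt(Hz) density over 3-30 MHz integrates to 7.79 Pa, i.e.
#' 8 Pa to the nearest pascal). Masked bins inside the band are bridged by
#' linear interpolation with a warning.
#'
#' @param nepd an `nepd_spectrum` (from [nepd_spectrum()]) or a
#'   [spectral_density()] in Pa/sqrt(Hz).
#' @param band integration band in Hz; defaults to the spectrum's valid band.
#' @return r.m.s. NEP in Pa.
#' @export
rms_nep <- function(nepd, band = NULL) {
  if (inherits(nepd, "nepd_spectrum")) {
    freqs <- nepd$freqs; vals <- nepd$nepd
    if (is.null(band)) band <- nepd$band
  } else if (inherits(nepd, "spectral_density")) {
    freqs <- nepd$freqs; vals <- nepd$values
    if (is.null(band)) band <- range(freqs)
  } else stop("nepd must be an nepd_spectrum or spectral_density")
  band <- sort(band)
  if (band[1] < min(freqs) || band[2] > max(freqs))
    stop("integration band outside the spectrum grid")
  if (anyNA(vals)) {
    ok <- !is.na(vals)
    if (any(is.na(vals[freqs >= band[1] & freqs <= band[2]])))
      warning("masked bins inside the band bridged by interpolation")
    vals <- stats::approx(freqs[ok], vals[ok], xout = freqs, rule = 2)$y
  }
  inner <- freqs > band[1] & freqs < band[2]
  f <- c(band[1], freqs[inner], band[2])
  v <- stats::approx(freqs, vals, xout = f, rule = 2)$y
  sqrt(pracma::trapz(f, v^2))
}

#' Sensitivity of a resonator-type optical ultrasound sensor
#'
#' Closed-form noise-equivalent pressure density of a slope-interrogated
#' optical resonator,
#' `NEPD = (4*sqrt(3)*Ni / (9*Qc) + Nq / G) / Sm`,
#' provided as a comparison utility against the heterodyne laser sensor: with
#' `Ni = 0` it reduces to `Nq / (G * Sm)`, the laser-sensor form with
#' `Theta = G * Sm`.
#'
#' @param Ni in-phase (amplitude) noise density, rad-equivalent (1/sqrt(Hz)).
#' @param Nq quadrature phase-noise density (rad/sqrt(Hz)).
#' @param Qc resonator quality factor (> 0).
#' @param G frequency-ratio gain (> 0).
#' @param Sm acoustic modulation coefficient (1/Pa, > 0).
#' @return NEPD in Pa/sqrt(Hz); vectorized over its arguments.
#' @export
resonator_nepd <- function(Ni, Nq, Qc, G, Sm) {
  if (any(Ni < 0) || any(Nq < 0)) stop("noise densities must be non-negative")
  if (any(Qc <= 0) || any(G <= 0) || any(Sm <= 0))
    stop("Qc, G and Sm must be positive")
  (4 * sqrt(3) * Ni / (9 * Qc) + Nq / G) / Sm
}

#' Average repeated pulse acquisitions
#'
#' Coherent mean of repeated [time_trace()] acquisitions of the same event
#' (the sqrt(N) noise-averaging step of the calibration workflow).
#'
#' @param traces list of [time_trace()] objects with identical grids.
#' @return The averaged [time_trace()].
#' @export
average_traces <- function(traces) {
  stopifnot(length(traces) >= 1L)
  n <- length(traces[[1]]$samples)
  for (tr in traces) {
    stopifnot(inherits(tr, "time_trace"), length(tr$samples) == n,
              tr$sample_rate == traces[[1]]$sample_rate)
  }
  avg <- Reduce(`+`, lapply(traces, function(tr) tr$samples)) / length(traces)
  time_trace(avg, traces[[1]]$sample_rate, traces[[1]]$unit, traces[[1]]$t0)
}
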