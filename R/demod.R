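#' I/Q demodulation configuration
#'
#' Receiver settings for recovering the instantaneous carrier phase: the
#' intermediate frequency, the demodulation (low-pass) bandwidth, the analysis
#' band used when converting phase back to pressure, and phase unwrapping.
#'
#' @param f_if intermediate carrier frequency (Hz).
#' @param lowpass_cut demodulation low-pass cutoff (Hz, default 200 MHz). At
#'   filter-design time the effective cut is additionally capped at
#'   `0.95 * f_if` and `0.45 * sample_rate`: a cut at or above `f_if` would
#'   pass the `2 f_if` mixing image into the phase estimate.
#' @param analysis_band length-2 numeric, the pressure-reconstruction band in
#'   Hz (default 3-30 MHz).
#' @param unwrap_enabled unwrap the four-quadrant arctangent output.
#' @param filter_taps FIR low-pass length (odd; zero-phase forward-backward
#'   application, transients of `2 * filter_taps` samples trimmed at both
#'   ends).
#' @param rf_prefilter band-limit the carrier to `f_if +/- lowpass_cut` before
#'   mixing, as a receiver front end would; without it, broadband noise
#'   sidebands around the `2 f_if` mixing image fold into the baseband phase.
#' @return An object of class `demod_config`.
#' @export
demod_config <- function(f_if = 50e6, lowpass_cut = 200e6,
                         analysis_band = c(3e6, 30e6),
                         unwrap_enabled = TRUE, filter_taps = 129L,
                         rf_prefilter = TRUE) {
  stopifnot(f_if > 0, lowpass_cut > 0, length(analysis_band) == 2L,
            analysis_band[1] > 0, analysis_band[2] > analysis_band[1],
            filter_taps >= 7L)
  if (filter_taps %% 2 == 0) filter_taps <- filter_taps + 1L
  structure(list(f_if = f_if, lowpass_cut = lowpass_cut,
                 analysis_band = analysis_band,
                 unwrap_enabled = unwrap_enabled,
                 filter_taps = as.integer(filter_taps),
                 rf_prefilter = isTRUE(rf_prefilter)),
            class = "demod_config")
}

#' @export
print.demod_config <- function(x, ...) {
  cat(sprintf(
    "<demod_config> f_if = %.4g MHz, lowpass %.4g MHz, band %.3g-%.3g MHz, unwrap %s, %d taps\n",
    x$f_if / 1e6, x$lowpass_cut / 1e6, x$analysis_band[1] / 1e6,
    x$analysis_band[2] / 1e6, x$unwrap_enabled, x$filter_taps))
  invisible(x)
}

## Mix, low-pass and trim: returns list(I, Q, t0, fs) of the baseband pair.
iq_baseband <- function(carrier, cfg) {
  stopifnot(inherits(carrier, "time_trace"))
  if (is.complex(carrier$samples)) stop("carrier must be real-valued")
  fs <- carrier$sample_rate
  if (cfg$f_if >= fs / 2) stop("f_if violates Nyquist for this carrier")
  taps <- cfg$filter_taps
  n <- length(carrier$samples)
  if (n <= 5L * taps)
    stop("carrier shorter than the demodulation filter transient")
  cut <- min(cfg$lowpass_cut, 0.95 * cfg$f_if, 0.45 * fs)
  t <- trace_times(carrier)
  x <- Re(carrier$samples)
  if (cfg$rf_prefilter) {
    lo <- max(cfg$f_if - cut, 0.01 * fs / 2)
    hi <- min(cfg$f_if + cut, 0.99 * fs / 2)
    bp <- signal::fir1(taps - 1L, c(lo, hi) / (fs / 2), type = "pass")
    x <- signal::filtfilt(bp, x)
  }
  b <- signal::fir1(taps - 1L, cut / (fs / 2), type = "low")
  I <- signal::filtfilt(b, 2 * x * cos(2 * pi * cfg$f_if * t))
  Q <- signal::filtfilt(b, -2 * x * sin(2 * pi * cfg$f_if * t))
  keep <- (2L * taps + 1L):(n - 2L * taps)
  list(I = I[keep], Q = Q[keep], t0 = t[keep[1]], fs = fs)
}

#' I/Q phase demodulation of the heterodyne carrier
#'
#' Band-limits the carrier around `f_if` (receiver front end, see
#' [demod_config()]), mixes it with cosine and sine replicas at `f_if`,
#' low-passes both paths (linear-phase FIR applied forward-backward so arrival
#' times are not biased; `2 * filter_taps` samples trimmed at each end), and
#' retrieves the
#' instantaneous phase as the four-quadrant arctangent `atan2(Q, I)`. The phase
#' is unwrapped when enabled and the best-fit linear ramp (residual carrier
#' frequency offset plus constant) is removed. For a carrier from
#' [synthesize_beat()] the output equals the doubled acoustic modulation
#' `2 * dtheta(t)` plus noise; amplitude modulation is rejected by the
#' arctangent.
#'
#' Samples where both `I` and `Q` vanish return phase 0 with a warning.
#'
#' @param carrier a real [time_trace()] (unit `"carrier"`).
#' @param cfg a [demod_config()].
#' @return A [time_trace()] with unit `"rad"` (shorter than the input by
#'   `4 * filter_taps` samples; `t0` is advanced accordingly).
#' @export
iq_demodulate <- function(carrier, cfg) {
  bb <- iq_baseband(carrier, cfg)
  zero <- bb$I == 0 & bb$Q == 0
  if (any(zero)) warning("I/Q both zero at some samples; phase set to 0 there")
  ph <- atan2(bb$Q, bb$I)
  ph[zero] <- 0
  if (cfg$unwrap_enabled) ph <- phase_unwrap(ph)
  ## Residual f_if mismatch and theta0 appear as a linear ramp, not signal.
  tt <- seq_along(ph) / bb$fs
  fit <- stats::lm.fit(cbind(1, tt), ph)
  time_trace(fit$residuals, bb$fs, "rad", bb$t0)
}

#' Convert demodulated phase to calibrated pressure
#'
#' Frequency-domain inversion of the phase response: within the analysis band
#' each spectral component of the (doubled) phase trace is divided by
#' `Theta(Omega) = 2 S_m(Omega) G(Omega)` and rotated by -pi/2 (undoing the
#' quadrature relation of the forward transduction); outside the band the
#' output is zeroed.
#'
#' @param dtheta a [time_trace()] in rad carrying the doubled modulation (as
#'   produced by [iq_demodulate()]).
#' @param spec the [sensor_spec()] describing the transducing sensor.
#' @param analysis_band length-2 band (Hz) retained in the inversion.
#' @return A band-limited [time_trace()] in Pa.
#' @export
phase_to_pressure <- function(dtheta, spec, analysis_band = c(3e6, 30e6)) {
  stopifnot(inherits(dtheta, "time_trace"))
  if (dtheta$unit != "rad") stop("phase_to_pressure expects a trace in rad")
  band <- sort(analysis_band)
  th_min <- min(phase_response_spectrum(spec, 2 * pi * band))
  if (!is.finite(th_min) || th_min <= 0)
    stop("configuration error: Theta(Omega) vanishes inside the analysis band")
  y <- apply_quadrature_transfer(
    Re(dtheta$samples), dtheta$sample_rate,
    function(Om) {
      f <- Om / (2 * pi)
      out <- numeric(length(Om))
      inb <- f >= band[1] & f <= band[2]
      out[inb] <- 1 / phase_response_spectrum(spec, Om[inb])
      out
    },
    rotate = -1i
  )
  time_trace(y, dtheta$sample_rate, "Pa", dtheta$t0)
}

## Goertzel-style single-bin amplitude over an integer number of periods.
tone_amplitude <- function(x, fs, f) {
  n <- length(x)
  t <- (0:(n - 1)) / fs
  Mod(2 * mean(x * exp(-2i * pi * f * t)))
}

#' Harmonic distortion of the recovered tone versus drive pressure
#'
#' For each drive amplitude, synthesizes a single-tone pressure stimulus,
#' passes it through the full transduction chain (phase modulation, noise-free
#' carrier, I/Q demodulation) and reports the total harmonic distortion of the
#' recovered phase: `THD = sqrt(sum_k A_k^2, k >= 2) / A_1` over harmonics
#' 2..6 of the stimulus tone. Used to locate the linearity limit of a
#' configuration: the wideband arctangent receiver stays linear far beyond the
#' small-angle regime (`dtheta << pi/6`), whereas a small-angle (linearized)
#' receiver, selected with `demodulator = "small_angle"`, distorts once the
#' doubled modulation index approaches a radian.
#'
#' @param p0_list numeric vector of drive pressure amplitudes (Pa).
#' @param spec a [sensor_spec()].
#' @param cfg a [demod_config()].
#' @param f_tone stimulus frequency (Hz).
#' @param n_cycles number of stimulus periods to simulate.
#' @param sample_rate simulation rate (Hz); default `5 * cfg$f_if`.
#' @param demodulator `"arctan"` (four-quadrant phase) or `"small_angle"`
#'   (quadrature-only linearized receiver).
#' @return A data.frame with columns `p0`, `beta` (doubled modulation index,
#'   rad) and `thd` (distortion fraction).
#' @export
harmonic_distortion <- function(p0_list, spec, cfg, f_tone = 10e6,
                                n_cycles = 120, sample_rate = NULL,
                                demodulator = c("arctan", "small_angle")) {
  demodulator <- match.arg(demodulator)
  fs <- if (is.null(sample_rate)) 5 * cfg$f_if else sample_rate
  duration <- n_cycles / f_tone
  beta0 <- 2 * sm_spectrum(spec, 2 * pi * f_tone) *
    gain_factor(spec, 2 * pi * f_tone)
  out <- lapply(p0_list, function(p0) {
    p <- tone_trace(acoustic_tone(p0, 2 * pi * f_tone), fs, duration)
    dth <- pressure_to_phase(spec, p)
    car <- synthesize_beat(spec, dth, f_if = cfg$f_if, rng_seed = 1L,
                           include_noise = FALSE)
    ph <- if (demodulator == "arctan") {
      iq_demodulate(car, cfg)
    } else {
      bb <- iq_baseband(car, cfg)
      ## lock the working point to quadrature, then take sin(phi) as phi
      z <- complex(real = bb$I, imaginary = bb$Q) *
        exp(-1i * atan2(mean(bb$Q), mean(bb$I)))
      a0 <- sqrt(mean(Mod(z)^2))
      ph0 <- Im(z) / a0
      time_trace(ph0 - mean(ph0), bb$fs, "rad", bb$t0)
    }
    ## analyze an interior whole number of periods
    nper <- floor(length(ph$samples) * f_tone / fs) - 2L
    if (nper < 4L) stop("trace too short for distortion analysis")
    i0 <- floor((length(ph$samples) - nper * fs / f_tone) / 2)
    x <- ph$samples[i0 + seq_len(round(nper * fs / f_tone))]
    amps <- vapply(1:6, function(k) tone_amplitude(x, fs, k * f_tone), 0)
    data.frame(p0 = p0, beta = p0 * beta0,
               thd = sqrt(sum(amps[-1]^2)) / amps[1])
  })
  do.call(rbind, out)
}
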