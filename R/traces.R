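#' Uniformly sampled signal trace
#'
#' Container for a uniformly sampled real- or complex-valued signal with its
#' sample rate, a unit tag and a start time. This is the common currency of the
#' whole detection chain: pressure waveforms (`"Pa"`), laser phase variations
#' (`"rad"`), synthesized heterodyne carriers (`"carrier"`) and hydrophone
#' voltages (`"V"`) are all `time_trace` objects.
#'
#' @param samples numeric or complex vector of samples (length >= 1).
#' @param sample_rate sampling rate in Hz (> 0).
#' @param unit unit tag, one of `"Pa"`, `"rad"`, `"carrier"`, `"V"`.
#' @param t0 start time in seconds of the first sample.
#' @return An object of class `time_trace`.
#' @examples
#' tr <- time_trace(sin(2 * pi * 5e6 * seq(0, 1e-6, by = 4e-9)), 250e6, "Pa")
#' trace_duration(tr)
#' @export
time_trace <- function(samples, sample_rate, unit = c("Pa", "rad", "carrier", "V"),
                       t0 = 0) {
  unit <- match.arg(unit)
  if (length(samples) < 1L) stop("time_trace requires at least one sample")
  if (!is.numeric(samples) && !is.complex(samples))
    stop("samples must be numeric or complex")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(
    list(samples = samples, sample_rate = sample_rate, unit = unit, t0 = t0),
    class = "time_trace"
  )
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf(
    "<time_trace> %d samples @ %.4g MS/s, unit '%s', t0 = %.4g s, duration %.4g s\n",
    length(x$samples), x$sample_rate / 1e6, x$unit, x$t0, trace_duration(x)
  ))
  invisible(x)
}

#' @export
length.time_trace <- function(x) length(x$samples)

#' @export
as.data.frame.time_trace <- function(x, ...) {
  data.frame(time = trace_times(x), value = x$samples)
}

#' Sample times of a trace
#' @param trace a [time_trace()].
#' @return Numeric vector of sample times (s).
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$sample_rate
}

#' Trace duration in seconds
#' @param trace a [time_trace()].
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$sample_rate

#' Root-mean-square value of a trace
#' @param trace a [time_trace()].
#' @export
trace_rms <- function(trace) sqrt(mean(Mod(trace$samples)^2))

#' Crop a trace to a time window
#' @param trace a [time_trace()].
#' @param tmin,tmax window limits (s), inclusive, relative to absolute time.
#' @return A [time_trace()] restricted to `[tmin, tmax]`.
#' @export
trace_crop <- function(trace, tmin = -Inf, tmax = Inf) {
  tt <- trace_times(trace)
  keep <- tt >= tmin & tt <= tmax
  if (!any(keep)) stop("crop window contains no samples")
  time_trace(trace$samples[keep], trace$sample_rate, trace$unit, t0 = tt[which(keep)[1]])
}

#' One-sided spectral density
#'
#' Amplitude spectral density on a strictly increasing one-sided frequency
#' grid, with a unit tag such as `"rad Hz^-1/2"`, `"Pa Hz^-1/2"` or `"rad/Pa"`.
#' Masked bins (e.g. where a calibration reference had no energy) are `NA`.
#'
#' @param freqs frequency grid in Hz, strictly increasing.
#' @param values amplitude-density values (same length as `freqs`; `NA` allowed
#'   for masked bins).
#' @param unit unit tag string.
#' @return An object of class `spectral_density`.
#' @export
spectral_density <- function(freqs, values, unit) {
  if (length(freqs) != length(values))
    stop("freqs and values must have equal length")
  if (length(freqs) > 1L && any(diff(freqs) <= 0))
    stop("freqs must be strictly increasing")
  if (any(values < 0, na.rm = TRUE))
    stop("amplitude densities must be non-negative")
  structure(list(freqs = freqs, values = values, unit = unit),
            class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf(
    "<spectral_density> %d bins, %.4g-%.4g MHz, unit '%s'%s\n",
    length(x$freqs), min(x$freqs) / 1e6, max(x$freqs) / 1e6, x$unit,
    if (anyNA(x$values)) sprintf(" (%d masked)", sum(is.na(x$values))) else ""
  ))
  invisible(x)
}

#' @export
as.data.frame.spectral_density <- function(x, ...) {
  data.frame(freq_hz = x$freqs, value = x$values, unit = x$unit)
}

## Analytic-signal envelope via the frequency-domain Hilbert construction:
## negative frequencies zeroed, positive doubled.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Envelope of a real trace
#'
#' Magnitude of the analytic signal, used for arrival-time extraction.
#' @param trace a real-valued [time_trace()].
#' @return A [time_trace()] with the same unit holding the envelope.
#' @export
trace_envelope <- function(trace) {
  env <- Mod(analytic_signal(Re(trace$samples)))
  time_trace(env, trace$sample_rate, trace$unit, trace$t0)
}

## Simple phase unwrapping: remove 2*pi jumps in successive differences.
phase_unwrap <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

## Seeded evaluation helper: all stochastic operations take an explicit seed;
## NULL means "use the current RNG stream".
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

## Frequency below which `frac` of the spectral energy of x lies (one-sided).
spectral_energy_edge <- function(x, fs, frac = 0.99) {
  if (all(x == 0)) return(0)
  n <- length(x)
  X <- Mod(stats::fft(x))^2
  half <- X[seq_len(floor(n / 2) + 1L)]
  f <- (seq_along(half) - 1L) * fs / n
  cum <- cumsum(half) / sum(half)
  f[which(cum >= frac)[1]]
}
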