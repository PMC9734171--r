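## Speed of light in vacuum (m/s).
.c0 <- 299792458

#' Laser ultrasound sensor specification
#'
#' Physical and optical parameters of the dual-polarization fiber-laser
#' ultrasound sensor. An incident pressure wave modulates the round-trip
#' optical path (`dL/dp = Sm * L_opt`), which shifts the lasing frequency
#' (`dw0/dL = -w0/L_opt`) and hence phase-modulates the laser output. The two
#' orthogonally polarized modes beat at `omega_b` on the photodetector; the
#' acoustic phase modulation appears doubled on that carrier because the
#' torsional-radial fiber deformation drives the two polarizations with
#' opposite sign.
#'
#' The lasing frequency must satisfy the cavity resonance condition
#' `(omega0/c0) * L_opt = m * 2*pi` for some positive integer `m`. With
#' `snap_resonance = TRUE` (default) `omega0` is snapped to the nearest exact
#' resonance (a relative adjustment below 1e-4 for the defaults); `m` itself is
#' implied, never stored.
#'
#' Defaults: a 2 mm grating pair gives a 4 mm physical round trip; with
#' effective index 1.468 the optical path is `L_opt = 5.87e-3` m. The lasing
#' frequency is 193 THz (1550 nm), the polarization beat 1.74 GHz, the acoustic
#' modulation coefficient `Sm_base = 1e-6` 1/Pa with a mechanical resonance of
#' the silica fiber at 22 MHz, and a measured-flat quadrature phase-noise
#' density of 1.5e-7 rad/sqrt(Hz).
#'
#' @param L_opt round-trip optical path length (m).
#' @param omega0 lasing angular frequency (rad/s).
#' @param Sm_base baseline (low-frequency) acoustic modulation coefficient (1/Pa).
#' @param f_res mechanical resonance frequency (Hz); `Inf` gives a flat
#'   `S_m` spectrum.
#' @param Q_res resonance quality factor (dimensionless).
#' @param omega_b polarization beat angular frequency (rad/s); retained as
#'   metadata, the simulated carrier lives at a configurable intermediate
#'   frequency (see [synthesize_beat()]).
#' @param Nq_density quadrature (phase) noise amplitude density (rad/sqrt(Hz)).
#' @param Ni_density in-phase (relative amplitude) noise density (1/sqrt(Hz)).
#' @param f_relax relaxation-oscillation frequency of the sensor laser (Hz).
#' @param relax_depth relative intensity-modulation depth at `f_relax`.
#' @param noise_corner optional 1/f phase-noise corner frequency (Hz); 0
#'   disables the low-frequency excess (default).
#' @param snap_resonance snap `omega0` to the nearest exact cavity resonance.
#' @return An object of class `sensor_spec`.
#' @examples
#' spec <- sensor_spec()
#' gain_factor(spec, 2 * pi * 10e6)
#' @export
sensor_spec <- function(L_opt = 5.87e-3,
                        omega0 = 2 * pi * 193e12,
                        Sm_base = 1e-6,
                        f_res = 22e6,
                        Q_res = 5,
                        omega_b = 2 * pi * 1.74e9,
                        Nq_density = 1.5e-7,
                        Ni_density = 1e-7,
                        f_relax = 1.7e6,
                        relax_depth = 0,
                        noise_corner = 0,
                        snap_resonance = TRUE) {
  stopifnot(L_opt > 0, omega0 > 0, omega_b > 0, Sm_base > 0,
            f_res > 0, Q_res > 0, Nq_density >= 0, Ni_density >= 0,
            f_relax > 0, relax_depth >= 0, noise_corner >= 0)
  if (snap_resonance) {
    m <- max(1, round(omega0 * L_opt / (2 * pi * .c0)))
    omega0 <- m * 2 * pi * .c0 / L_opt
  }
  structure(
    list(L_opt = L_opt, omega0 = omega0, Sm_base = Sm_base, f_res = f_res,
         Q_res = Q_res, omega_b = omega_b, Nq_density = Nq_density,
         Ni_density = Ni_density, f_relax = f_relax, relax_depth = relax_depth,
         noise_corner = noise_corner),
    class = "sensor_spec"
  )
}

#' @export
print.sensor_spec <- function(x, ...) {
  m <- round(x$omega0 * x$L_opt / (2 * pi * .c0))
  cat(sprintf(
    paste0("<sensor_spec> f0 = %.6g THz (cavity order m = %d), L_opt = %.3g mm\n",
           "  Sm = %.3g /Pa, resonance %.3g MHz (Q = %.3g), beat %.4g GHz\n",
           "  Nq = %.3g rad/sqrt(Hz), Ni = %.3g /sqrt(Hz), relax %.3g MHz (depth %.3g)\n"),
    x$omega0 / (2 * pi * 1e12), m, x$L_opt * 1e3,
    x$Sm_base, x$f_res / 1e6, x$Q_res, x$omega_b / (2 * pi * 1e9),
    x$Nq_density, x$Ni_density, x$f_relax / 1e6, x$relax_depth
  ))
  invisible(x)
}

#' Single-frequency acoustic tone
#'
#' Convenience description of a sinusoidal pressure wave
#' `p(t) = -p0 * cos(Omega * t + phase)`.
#'
#' @param p0 pressure amplitude (Pa, >= 0).
#' @param Omega angular frequency (rad/s, > 0).
#' @param phase phase offset (rad).
#' @return An object of class `acoustic_tone`.
#' @export
acoustic_tone <- function(p0, Omega, phase = 0) {
  stopifnot(p0 >= 0, Omega > 0)
  structure(list(p0 = p0, Omega = Omega, phase = phase), class = "acoustic_tone")
}

#' Render an acoustic tone as a pressure trace
#'
#' @param tone an [acoustic_tone()].
#' @param sample_rate sampling rate (Hz).
#' @param duration trace duration (s).
#' @param t0 start time (s).
#' @return A [time_trace()] in Pa holding `-p0 * cos(Omega t + phase)`.
#' @export
tone_trace <- function(tone, sample_rate, duration, t0 = 0) {
  t <- t0 + seq(0, duration - 1 / sample_rate, by = 1 / sample_rate)
  time_trace(-tone$p0 * cos(tone$Omega * t + tone$phase), sample_rate, "Pa", t0)
}

#' Frequency-ratio gain of phase transduction
#'
#' The lasing-frequency shift induced by the pressure wave integrates into the
#' laser phase, amplifying the acoustic response by `G(Omega) = omega0 / Omega`
#' -- the ratio of the optical carrier to the acoustic frequency. For a 200 THz
#' carrier and 10 MHz ultrasound the gain is 2e7.
#'
#' @param spec a [sensor_spec()].
#' @param Omega acoustic angular frequency (rad/s, > 0); vectorized.
#' @return Dimensionless gain `omega0 / Omega`.
#' @export
gain_factor <- function(spec, Omega) {
  if (any(Omega <= 0)) stop("Omega must be positive")
  spec$omega0 / Omega
}

#' Acoustic modulation coefficient spectrum S_m(Omega)
#'
#' The path-modulation coefficient is modeled as the baseline value shaped by
#' a single-pole mechanical resonance with unit low-frequency gain:
#' `S_m(Omega) = Sm_base * |H(Omega)|` with
#' `|H| = 1 / sqrt((1 - r^2)^2 + (r/Q)^2)`, `r = f / f_res`. At `f = f_res`
#' the magnitude is exactly `Q_res`; well above resonance it rolls off
#' monotonically. `f_res = Inf` gives a flat spectrum.
#'
#' @inheritParams gain_factor
#' @return `S_m(Omega)` in 1/Pa; vectorized over `Omega`.
#' @export
sm_spectrum <- function(spec, Omega) {
  if (any(Omega <= 0)) stop("Omega must be positive")
  if (!is.finite(spec$f_res)) return(rep(spec$Sm_base, length(Omega)))
  r <- Omega / (2 * pi * spec$f_res)
  spec$Sm_base / sqrt((1 - r^2)^2 + (r / spec$Q_res)^2)
}

#' Phase response spectrum Theta(Omega)
#'
#' Phase modulation of the heterodyne carrier per unit pressure,
#' `Theta(Omega) = 2 * S_m(Omega) * G(Omega)` (rad/Pa). The factor 2 reflects
#' the opposite phase changes of the two polarization modes, which double the
#' modulation seen on the beat signal.
#'
#' @inheritParams gain_factor
#' @return `Theta(Omega)` in rad/Pa; vectorized over `Omega`.
#' @export
phase_response_spectrum <- function(spec, Omega) {
  2 * sm_spectrum(spec, Omega) * gain_factor(spec, Omega)
}

## White Gaussian noise of one-sided amplitude density `density`, brick-wall
## band-limited to |f| <= B. Keeping the modulation sidebands below Nyquist
## (B < min(f_if, fs/2 - f_if)) prevents alias folding around the carrier,
## which would decorrelate the AM sidebands and inflate the in-band density.
bandlimited_white <- function(n, fs, density, B) {
  x <- stats::rnorm(n, 0, density * sqrt(fs / 2))
  if (B >= fs / 2) return(x)
  X <- stats::fft(x)
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  X[f > B] <- 0
  Re(stats::fft(X, inverse = TRUE) / n)
}

## Apply a frequency-domain quadrature transfer to a real trace:
## each positive-frequency component is scaled by gainfun(Omega) and rotated by
## `rotate` (+1i is the +pi/2 quadrature shift); DC and the Nyquist bin map to 0.
apply_quadrature_transfer <- function(x, fs, gainfun, rotate = 1i) {
  n <- length(x)
  X <- stats::fft(x)
  X[1] <- 0
  kmax <- floor((n - 1) / 2)
  if (kmax >= 1) {
    k <- seq_len(kmax)
    g <- gainfun(2 * pi * k * fs / n)
    X[k + 1L] <- X[k + 1L] * g * rotate
    X[n + 1L - k] <- Conj(X[k + 1L])
  }
  if (n %% 2 == 0) X[n / 2 + 1L] <- 0
  Re(stats::fft(X, inverse = TRUE) / n)
}

#' Pressure to laser phase transduction
#'
#' Converts a pressure trace into the acoustically induced laser phase
#' variation. In the frequency domain each spectral component of `p` is scaled
#' by `S_m(Omega) * G(Omega)` and shifted by +pi/2 (the sine-vs-cosine
#' quadrature relation of frequency-to-phase integration: the tone
#' `p = -p0 cos(Omega t)` induces `dtheta = p0 Sm G sin(Omega t)`). The DC
#' component maps to zero.
#'
#' The returned trace is the single-polarization phase; the heterodyne carrier
#' carries `+dtheta` and `-dtheta` on the two polarizations, so the beat-signal
#' modulation is `2 * dtheta` (use `doubled = TRUE` to obtain that reference
#' directly).
#'
#' @param spec a [sensor_spec()].
#' @param p a [time_trace()] with unit `"Pa"`.
#' @param doubled if `TRUE`, return the doubled modulation `2 * dtheta` seen by
#'   the heterodyne receiver.
#' @return A [time_trace()] with unit `"rad"`.
#' @export
pressure_to_phase <- function(spec, p, doubled = FALSE) {
  stopifnot(inherits(p, "time_trace"))
  if (p$unit != "Pa") stop("pressure_to_phase expects a trace in Pa")
  if (length(p$samples) == 0L) stop("empty trace")
  scale <- if (doubled) 2 else 1
  y <- apply_quadrature_transfer(
    Re(p$samples), p$sample_rate,
    function(Om) scale * sm_spectrum(spec, Om) * gain_factor(spec, Om),
    rotate = 1i
  )
  time_trace(y, p$sample_rate, "rad", p$t0)
}

#' Synthesize the heterodyne beat carrier
#'
#' Builds the real radio-frequency carrier seen by the receiver,
#' `v(t) = A(t) * cos(2 pi f_if t + 2 dtheta(t) + theta0 + phi_n(t))`, where
#' the doubled acoustic phase modulation rides on an intermediate-frequency
#' carrier. Simulating the physical 1.74 GHz beat directly would be wasteful;
#' the receiver downshifts it to baseband anyway, so the carrier is synthesized
#' at a configurable IF (`f_if`, default 50 MHz at a 250 MS/s grid) and
#' `omega_b` stays in the [sensor_spec()] as metadata.
#'
#' Noise model: multiplicative intensity noise
#' `A(t) = 1 + relax_depth * sin(2 pi f_relax t) + n_i(t)` with white relative
#' amplitude noise of density `Ni_density`, plus additive white quadrature
#' phase noise of density `Nq_density` (optionally with 1/f excess below
#' `noise_corner`). The carrier start phase `theta0` is drawn uniformly on
#' `[0, 2 pi)` from the seeded generator.
#'
#' The carrier must clear the modulation band: the synthesis errors out unless
#' `f_if` exceeds the 99%-energy bandwidth of `dtheta` and
#' `f_if + bandwidth` respects Nyquist. (Choose `f_if` at least twice the
#' maximum signal frequency for clean separation.)
#'
#' @param spec a [sensor_spec()].
#' @param dtheta single-polarization phase trace (rad) from
#'   [pressure_to_phase()]; the carrier applies the doubled modulation.
#' @param f_if intermediate carrier frequency (Hz).
#' @param rng_seed integer seed for `theta0` and the noise realizations;
#'   `NULL` uses the current RNG stream.
#' @param include_noise if `FALSE`, suppress all noise terms (theta0 is still
#'   drawn, deterministically under the seed).
#' @param drift_hz optional numeric vector (length of the trace) of
#'   instantaneous carrier-frequency offsets in Hz, integrated into a
#'   common-mode carrier phase drift (applied before phase doubling, i.e. not
#'   doubled) -- used to emulate slow thermal/rotational perturbations.
#' @return A [time_trace()] with unit `"carrier"`.
#' @export
synthesize_beat <- function(spec, dtheta, f_if = 50e6, rng_seed = NULL,
                            include_noise = TRUE, drift_hz = NULL) {
  stopifnot(inherits(dtheta, "time_trace"))
  if (dtheta$unit != "rad") stop("dtheta must be a phase trace in rad")
  fs <- dtheta$sample_rate
  n <- length(dtheta$samples)
  if (f_if <= 0 || f_if >= fs / 2)
    stop("configuration error: f_if must lie inside (0, sample_rate/2)")
  f_max <- spectral_energy_edge(Re(dtheta$samples), fs, 0.99)
  if (f_max > 0 && (f_if <= f_max || f_if + f_max >= fs / 2))
    stop(sprintf(
      "configuration error: f_if = %.3g Hz does not clear the modulation band (99%% energy below %.3g Hz) within Nyquist",
      f_if, f_max))
  t <- trace_times(dtheta)
  drift_phase <- if (is.null(drift_hz)) 0 else {
    stopifnot(length(drift_hz) == n)
    2 * pi * cumsum(drift_hz) / fs
  }
  B <- min(f_if, fs / 2 - f_if)
  with_seed_or_current(rng_seed, {
    theta0 <- stats::runif(1, 0, 2 * pi)
    if (include_noise) {
      phase_noise <- bandlimited_white(n, fs, spec$Nq_density, B)
      if (spec$noise_corner > 0) {
        ## 1/f excess: shape white noise by sqrt(fc/f) below the corner.
        w <- bandlimited_white(n, fs, spec$Nq_density, B)
        W <- stats::fft(w)
        f <- pmin((0:(n - 1)), (n - (0:(n - 1)))) * fs / n
        shape <- ifelse(f > 0 & f < spec$noise_corner,
                        sqrt(spec$noise_corner / pmax(f, fs / n)) - 1, 0)
        phase_noise <- phase_noise + Re(stats::fft(W * shape, inverse = TRUE) / n)
      }
      amp_noise <- bandlimited_white(n, fs, spec$Ni_density, B)
      relax <- spec$relax_depth * sin(2 * pi * spec$f_relax * t)
    } else {
      phase_noise <- 0; amp_noise <- 0; relax <- 0
    }
    env <- 1 + relax + amp_noise
    ph <- 2 * pi * f_if * t + 2 * Re(dtheta$samples) + theta0 +
      drift_phase + phase_noise
    time_trace(env * cos(ph), fs, "carrier", dtheta$t0)
  })
}
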