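## Default speed of sound in the water coupling medium (m/s).
.c_sound_default <- 1500

## Package-local cache for the extinction table.
.paesim_env <- new.env(parent = emptyenv())

hb_extinction_table <- function() {
  if (is.null(.paesim_env$hb)) {
    path <- system.file("extdata", "hemoglobin_extinction.csv", package = "paesim")
    .paesim_env$hb <- utils::read.csv(path, comment.char = "#")
  }
  .paesim_env$hb
}

#' Molar extinction coefficients of hemoglobin
#'
#' Linear interpolation of the packaged oxy/deoxyhemoglobin extinction table.
#'
#' @param wavelength_m wavelength(s) in meters.
#' @return A list with numeric vectors `hbo2` and `hb` (cm^-1/M).
#' @export
hb_extinction <- function(wavelength_m) {
  tab <- hb_extinction_table()
  nm <- wavelength_m * 1e9
  if (any(nm < min(tab$wavelength_nm) | nm > max(tab$wavelength_nm)))
    stop("wavelength outside the packaged extinction table (520-580 nm)")
  list(
    hbo2 = stats::approx(tab$wavelength_nm, tab$eps_hbo2, xout = nm)$y,
    hb = stats::approx(tab$wavelength_nm, tab$eps_hb, xout = nm)$y
  )
}

#' Dual-wavelength optical excitation model
#'
#' Excitation parameters of the photoacoustic probe: the two interleaved
#' nanosecond pulse wavelengths (532 and 558 nm by default), their hemoglobin
#' extinction coefficients, the focused Gaussian beam (waist FWHM 7.4 um;
#' lateral FWHM grows with defocus `z` as
#' `FWHM(z) = waist * sqrt(1 + (z/rayleigh_range)^2)`), the per-pulse energy
#' and the wavelength interleave delay.
#'
#' The default Rayleigh-range parameter (119 um) is an independent beam
#' parameter rather than the diffraction-limited value of an ideal Gaussian, so
#' that measured depth-resolution figures (about 20 um at +/-300 um defocus for
#' a 7.4 um waist) are matched by configuration.
#'
#' @param wavelengths length-2 wavelengths in m (must be distinct).
#' @param eps_hbo2,eps_hb length-2 molar extinction coefficients at the two
#'   wavelengths; default looked up from the packaged table.
#' @param beam_waist_fwhm focal lateral FWHM (m).
#' @param rayleigh_range beam defocus scale (m).
#' @param pulse_energy per-pulse energy (J), scalar or length 2.
#' @param pulse_delay interleave delay between the two wavelengths (s);
#'   1500 ns for raster imaging, 2300 ns for rotational endoscopy.
#' @param pulse_fwhm emitted pressure-pulse envelope FWHM (s); the emitted
#'   waveform is a Gaussian derivative of this width.
#' @return An object of class `optical_model`.
#' @export
optical_model <- function(wavelengths = c(532e-9, 558e-9),
                          eps_hbo2 = NULL, eps_hb = NULL,
                          beam_waist_fwhm = 7.4e-6,
                          rayleigh_range = 119e-6,
                          pulse_energy = 250e-9,
                          pulse_delay = 1500e-9,
                          pulse_fwhm = 30e-9) {
  stopifnot(length(wavelengths) == 2L, wavelengths[1] != wavelengths[2],
            beam_waist_fwhm > 0, rayleigh_range > 0, all(pulse_energy > 0),
            pulse_delay > 0, pulse_fwhm > 0)
  if (is.null(eps_hbo2) || is.null(eps_hb)) {
    eps <- hb_extinction(wavelengths)
    if (is.null(eps_hbo2)) eps_hbo2 <- eps$hbo2
    if (is.null(eps_hb)) eps_hb <- eps$hb
  }
  stopifnot(all(eps_hbo2 > 0), all(eps_hb > 0),
            length(eps_hbo2) == 2L, length(eps_hb) == 2L)
  if (length(pulse_energy) == 1L) pulse_energy <- rep(pulse_energy, 2L)
  structure(
    list(wavelengths = wavelengths, eps_hbo2 = eps_hbo2, eps_hb = eps_hb,
         beam_waist_fwhm = beam_waist_fwhm, rayleigh_range = rayleigh_range,
         pulse_energy = pulse_energy, pulse_delay = pulse_delay,
         pulse_fwhm = pulse_fwhm),
    class = "optical_model"
  )
}

#' @export
print.optical_model <- function(x, ...) {
  cat(sprintf(
    "<optical_model> %.0f/%.0f nm, waist %.3g um (zR %.3g um), %.3g nJ, delay %.0f ns\n",
    x$wavelengths[1] * 1e9, x$wavelengths[2] * 1e9, x$beam_waist_fwhm * 1e6,
    x$rayleigh_range * 1e6, x$pulse_energy[1] * 1e9, x$pulse_delay * 1e9))
  invisible(x)
}

#' Lateral beam FWHM at a given defocus
#'
#' @param optical an [optical_model()].
#' @param defocus axial distance from the focal plane (m); vectorized.
#' @return Lateral FWHM in m; equals `beam_waist_fwhm` exactly at `defocus = 0`.
#' @export
beam_fwhm <- function(optical, defocus) {
  optical$beam_waist_fwhm * sqrt(1 + (defocus / optical$rayleigh_range)^2)
}

#' Scan geometry description
#'
#' Maps A-line index to spatial pose for the two scanning modes: 2-D `raster`
#' scanning of the probe over a plane, and `rotational` scanning (B-scans of
#' `alines_per_bscan` A-lines at `angle_step` degrees each) combined with a
#' constant pullback translation. For rotational scans the lateral arc step at
#' the focal plane is `working_distance * angle_step` (in radians): 4.8 um,
#' i.e. 5 um to the nearest micrometer, for the 2.75 mm working distance and
#' 0.1 degree default.
#'
#' @param mode `"rotational"` or `"raster"`.
#' @param angle_step rotational angle increment per A-line (degrees).
#' @param alines_per_bscan A-lines per rotational B-scan; the covered sector
#'   `alines_per_bscan * angle_step` must not exceed 360 degrees.
#' @param working_distance focal distance from the probe axis (m).
#' @param pullback_speed pullback translation speed (m/s).
#' @param bscan_rate B-scan repetition rate (Hz); with the pullback speed it
#'   sets the row pitch `pullback_speed / bscan_rate`.
#' @param raster_range length-2 raster extent (m).
#' @param raster_pixels raster grid size, scalar or length-2 (columns, rows).
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(mode = c("rotational", "raster"),
                          angle_step = 0.1,
                          alines_per_bscan = 2000L,
                          working_distance = 2.75e-3,
                          pullback_speed = 10e-6,
                          bscan_rate = 1,
                          raster_range = c(6e-3, 6e-3),
                          raster_pixels = c(1500L, 1500L)) {
  mode <- match.arg(mode)
  stopifnot(angle_step > 0, alines_per_bscan >= 1, working_distance > 0,
            pullback_speed > 0, bscan_rate > 0, all(raster_range > 0),
            all(raster_pixels >= 1))
  if (mode == "rotational" && alines_per_bscan * angle_step > 360)
    stop("rotational sector alines_per_bscan * angle_step exceeds 360 degrees")
  if (length(raster_range) == 1L) raster_range <- rep(raster_range, 2L)
  if (length(raster_pixels) == 1L) raster_pixels <- rep(raster_pixels, 2L)
  structure(
    list(mode = mode, angle_step = angle_step,
         alines_per_bscan = as.integer(alines_per_bscan),
         working_distance = working_distance,
         pullback_speed = pullback_speed, bscan_rate = bscan_rate,
         raster_range = raster_range, raster_pixels = as.integer(raster_pixels)),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  if (x$mode == "rotational") {
    cat(sprintf(
      "<scan_geometry> rotational: %d A-lines x %.3g deg (lateral step %.3g um), pullback pitch %.3g um\n",
      x$alines_per_bscan, x$angle_step, lateral_step(x) * 1e6,
      pullback_pitch(x) * 1e6))
  } else {
    cat(sprintf(
      "<scan_geometry> raster: %.3g x %.3g mm, %d x %d px (pitch %.3g um)\n",
      x$raster_range[1] * 1e3, x$raster_range[2] * 1e3,
      x$raster_pixels[1], x$raster_pixels[2], lateral_step(x) * 1e6))
  }
  invisible(x)
}

#' Lateral step of a scan geometry
#'
#' Arc-length spacing between adjacent A-lines at the focal plane: for a
#' rotational scan `working_distance * angle_step` (radians), for a raster
#' scan `raster_range / raster_pixels` along the fast axis.
#'
#' @param geometry a [scan_geometry()].
#' @return Lateral step in m.
#' @export
lateral_step <- function(geometry) {
  if (geometry$mode == "rotational") {
    geometry$working_distance * geometry$angle_step * pi / 180
  } else {
    geometry$raster_range[1] / geometry$raster_pixels[1]
  }
}

#' Pullback row pitch of a rotational scan
#'
#' @param geometry a rotational [scan_geometry()].
#' @return Axial distance between successive B-scans, `pullback_speed /
#'   bscan_rate`, in m.
#' @export
pullback_pitch <- function(geometry) {
  if (geometry$mode != "rotational") stop("pullback pitch applies to rotational scans")
  geometry$pullback_speed / geometry$bscan_rate
}

## Resample a polyline (n x 3 matrix) to roughly uniform spacing ds.
resample_polyline <- function(pts, ds) {
  if (nrow(pts) < 2L) return(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(pts[1, , drop = FALSE])
  sq <- seq(0, total, by = ds)
  cbind(stats::approx(s, pts[, 1], xout = sq)$y,
        stats::approx(s, pts[, 2], xout = sq)$y,
        stats::approx(s, pts[, 3], xout = sq)$y)
}

#' Single vessel segment
#'
#' @param centerline n x 3 matrix of centerline points (x, y, z in m; z is
#'   depth away from the probe).
#' @param radius vessel radius (m, > 0).
#' @param so2 oxygen saturation (fraction in `[0, 1]`).
#' @param c_hb relative total-hemoglobin concentration (arbitrary units).
#' @param kind free label (`"trunk"`, `"branch"`, `"capillary"`, ...).
#' @return An object of class `vessel_segment`.
#' @export
vessel_segment <- function(centerline, radius, so2, c_hb = 1, kind = "vessel") {
  centerline <- rbind(centerline)
  stopifnot(ncol(centerline) == 3L, radius > 0, so2 >= 0, so2 <= 1, c_hb >= 0)
  structure(list(centerline = centerline, radius = radius, so2 = so2,
                 c_hb = c_hb, kind = kind),
            class = "vessel_segment")
}

new_phantom <- function(kind, vessels = list(), edges = list(),
                        bounds = NULL) {
  structure(list(kind = kind, vessels = vessels, edges = edges,
                 bounds = bounds),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  if (x$kind == "vasculature") {
    cat(sprintf("<phantom> vasculature: %d vessel segments\n", length(x$vessels)))
  } else {
    cat(sprintf("<phantom> blade edge: %d edge(s)\n", length(x$edges)))
  }
  invisible(x)
}

#' Digital vasculature phantom
#'
#' Generates a deterministic-under-seed branching vessel tree in a slab:
#' trunk vessels crossing the field of view with gentle meanders, alternately
#' assigned arterial (high sO2) and venous (low sO2) saturations, with thinner
#' branch vessels sprouting from the trunks and capillaries from the branches
#' at intermediate saturations. Emulates the trunk-plus-branch vasculature of
#' rectal mucosa at the scale the endoscope images.
#'
#' @param rng_seed integer seed (same seed, identical phantom).
#' @param n_trunks number of trunk vessels (0 gives an empty phantom).
#' @param n_branches branches sprouted per trunk.
#' @param n_caps capillaries sprouted per branch.
#' @param bounds list with `x`, `y` (lateral extents, m) and `z` (depth band,
#'   m) of the slab.
#' @param trunk_radius,branch_radius,cap_radius length-2 radius ranges (m).
#' @param so2_artery,so2_vein,so2_cap length-2 sO2 ranges for arterial trunks
#'   (and their branches), venous trunks (and branches), and capillaries.
#' @return A `phantom` of kind `"vasculature"`.
#' @export
make_vessel_phantom <- function(rng_seed = 1L, n_trunks = 3L,
                                n_branches = 4L, n_caps = 2L,
                                bounds = list(x = c(0, 1.5e-3),
                                              y = c(0, 1.5e-3),
                                              z = c(0.9e-3, 1.3e-3)),
                                trunk_radius = c(30e-6, 50e-6),
                                branch_radius = c(12e-6, 25e-6),
                                cap_radius = c(5e-6, 10e-6),
                                so2_artery = c(0.92, 0.98),
                                so2_vein = c(0.60, 0.72),
                                so2_cap = c(0.75, 0.85)) {
  stopifnot(n_trunks >= 0, n_branches >= 0, n_caps >= 0)
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  vessels <- with_seed_or_current(rng_seed, {
    out <- list()
    if (n_trunks > 0) {
      xs <- seq(bounds$x[1], bounds$x[2],
                length.out = n_trunks + 2L)[2:(n_trunks + 1L)]
      for (i in seq_len(n_trunks)) {
        arterial <- i %% 2L == 1L
        yy <- seq(bounds$y[1], bounds$y[2], length.out = 40L)
        wig <- (bounds$x[2] - bounds$x[1]) * 0.04 *
          sin(2 * pi * yy / diff(range(yy)) * stats::runif(1, 0.5, 1.5) +
                stats::runif(1, 0, 2 * pi))
        z0 <- runif1(bounds$z)
        trunk_line <- cbind(xs[i] + wig, yy, z0 + 0 * yy)
        so2_rng <- if (arterial) so2_artery else so2_vein
        out[[length(out) + 1L]] <- vessel_segment(
          trunk_line, runif1(trunk_radius), runif1(so2_rng), 1, "trunk")
        for (b in seq_len(n_branches)) {
          j <- sample(5:35, 1L)
          p0 <- trunk_line[j, ]
          ang <- stats::runif(1, pi / 6, 5 * pi / 6) * sample(c(-1, 1), 1L)
          len <- stats::runif(1, 0.15, 0.35) * diff(bounds$x)
          dirv <- c(cos(ang), sin(ang), 0)
          tt <- seq(0, len, length.out = 12L)
          curve <- 0.1 * len * sin(pi * tt / len)
          branch_line <- cbind(p0[1] + dirv[1] * tt - dirv[2] * curve,
                               p0[2] + dirv[2] * tt + dirv[1] * curve,
                               p0[3] + stats::runif(1, -0.2, 0.2) * tt)
          so2_b <- max(0, min(1, runif1(so2_rng) + stats::rnorm(1, 0, 0.01)))
          out[[length(out) + 1L]] <- vessel_segment(
            branch_line, runif1(branch_radius), so2_b, 0.8, "branch")
          for (k in seq_len(n_caps)) {
            q0 <- branch_line[sample(3:10, 1L), ]
            ang2 <- stats::runif(1, 0, 2 * pi)
            len2 <- stats::runif(1, 0.05, 0.12) * diff(bounds$x)
            tt2 <- seq(0, len2, length.out = 6L)
            cap_line <- cbind(q0[1] + cos(ang2) * tt2,
                              q0[2] + sin(ang2) * tt2,
                              q0[3] + stats::runif(1, -0.3, 0.3) * tt2)
            out[[length(out) + 1L]] <- vessel_segment(
              cap_line, runif1(cap_radius), runif1(so2_cap), 0.6, "capillary")
          }
        }
      }
    }
    out
  })
  new_phantom("vasculature", vessels = vessels, bounds = bounds)
}

#' Blade-edge resolution phantom
#'
#' A thin absorbing half-plane with uniform absorption at both wavelengths,
#' used to measure lateral resolution from the edge-spread function. Several
#' `position` values give several parallel edges (absorptions add).
#'
#' @param position lateral coordinate(s) of the edge (m); the covered side is
#'   towards larger coordinates.
#' @param orientation `"x"` (edge normal along x, i.e. scan across x) or
#'   `"y"`; a 90-degree rotation swaps the axes.
#' @param depth depth of the absorbing layer (m).
#' @param strength relative absorption strength (scalar or one per edge).
#' @return A `phantom` of kind `"edge"`.
#' @export
make_blade_edge <- function(position = 0, orientation = c("x", "y"),
                            depth = 1e-3, strength = 1) {
  orientation <- match.arg(orientation)
  strength <- rep(strength, length.out = length(position))
  edges <- Map(function(p, s) list(position = p, orientation = orientation,
                                   depth = depth, strength = s),
               position, strength)
  new_phantom("edge", edges = edges)
}

## Gaussian-derivative pressure pulse template centered in its window,
## normalized to unit peak amplitude. `fwhm` is the width of the underlying
## Gaussian envelope.
pulse_template <- function(fs, fwhm, n) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  t <- ((0:(n - 1)) - floor(n / 2)) / fs
  s <- -t / sigma * exp(-t^2 / (2 * sigma^2))
  s / max(abs(s))
}

## Circular convolution with a centered kernel, preserving alignment.
conv_centered <- function(x, kernel) {
  n <- length(x)
  k <- length(kernel)
  kk <- numeric(n)
  half <- floor(k / 2)
  idx <- ((seq_len(k) - 1L - half) %% n) + 1L
  kk[idx] <- kk[idx] + kernel
  Re(stats::fft(stats::fft(x) * stats::fft(kk), inverse = TRUE) / n)
}

## Relative absorption coefficient of a vessel at wavelength index i,
## normalized so a pure-HbO2 vessel at the first wavelength has mu = c_hb.
mu_a_rel <- function(vessel, optical, i) {
  eps_ref <- optical$eps_hbo2[1]
  (optical$eps_hbo2[i] * vessel$so2 +
     optical$eps_hb[i] * (1 - vessel$so2)) * vessel$c_hb / eps_ref
}

#' Forward photoacoustic A-line at one probe pose
#'
#' Optical-resolution forward model for a single A-line: the focused Gaussian
#' beam at lateral pose `(x, y)` illuminates the phantom; absorbed energy
#' density along the beam (extinction-weighted hemoglobin for vasculature
#' phantoms, the covered beam fraction for blade edges) launches a
#' Gaussian-derivative pressure pulse per absorber whose arrival time is the
#' one-way acoustic flight `depth / c_sound`. The two excitation wavelengths
#' are fired `pulse_delay` apart and share one record, each occupying a window
#' of `pulse_delay` seconds.
#'
#' Amplitudes are relative: a pure-HbO2 absorber with `c_hb = 1`, fully inside
#' the beam at focus, produces a peak of about `amp_scale` Pa at the first
#' wavelength; other absorbers scale with extinction, beam overlap, radius and
#' pulse energy. The wavelength-amplitude ratio of any single absorber equals
#' its extinction ratio times the pulse-energy ratio.
#'
#' @param phantom a `phantom` from [make_vessel_phantom()] or
#'   [make_blade_edge()].
#' @param pose length-2 lateral beam position `(x, y)` in m.
#' @param optical an [optical_model()].
#' @param sample_rate acquisition rate (Hz).
#' @param c_sound speed of sound (m/s; water coupling).
#' @param focus_depth depth of the beam focus (m).
#' @param focus_offset extra defocus applied to the whole phantom (m); positive
#'   moves the focal plane shallower relative to the absorbers.
#' @param noise_rms additive white acoustic noise (Pa r.m.s.).
#' @param rng_seed seed for the noise realization.
#' @param amp_scale pressure scale (Pa) of a reference absorber.
#' @return A [time_trace()] in Pa of duration `2 * pulse_delay`.
#' @export
forward_aline <- function(phantom, pose, optical,
                          sample_rate = 250e6, c_sound = .c_sound_default,
                          focus_depth = 1.1e-3, focus_offset = 0,
                          noise_rms = 0, rng_seed = NULL,
                          amp_scale = 1e-3) {
  stopifnot(inherits(phantom, "phantom"), length(pose) == 2L,
            inherits(optical, "optical_model"))
  n_win <- round(optical$pulse_delay * sample_rate)
  z <- (0:(n_win - 1)) / sample_rate * c_sound
  dz <- c_sound / sample_rate
  if (!is.null(phantom$bounds)) {
    bx <- phantom$bounds$x; by <- phantom$bounds$y
    margin <- 5e-5
    if (pose[1] < bx[1] - margin || pose[1] > bx[2] + margin ||
        pose[2] < by[1] - margin || pose[2] > by[2] + margin) {
      warning("pose outside phantom bounds; returning empty trace")
      return(time_trace(numeric(2L * n_win), sample_rate, "Pa"))
    }
  }
  zfoc <- focus_depth + focus_offset
  tmpl <- pulse_template(sample_rate, optical$pulse_fwhm,
                         min(n_win, 8L * round(optical$pulse_fwhm * sample_rate) + 1L))
  e_ratio <- optical$pulse_energy / optical$pulse_energy[1]
  windows <- lapply(1:2, function(i) {
    A <- numeric(n_win)
    if (phantom$kind == "vasculature") {
      for (v in phantom$vessels) {
        ds <- max(v$radius / 2, 5e-6)
        pts <- resample_polyline(v$centerline, ds)
        d_lat <- sqrt((pts[, 1] - pose[1])^2 + (pts[, 2] - pose[2])^2)
        fw <- beam_fwhm(optical, pts[, 3] - zfoc)
        sigma_b <- fw / (2 * sqrt(2 * log(2)))
        ## beam-blurred vessel cross-section: the summed contributions of
        ## centerline points within the radius reproduce the chord profile,
        ## with edges softened over the local beam width
        w <- 0.5 * (1 + pracma::erf((v$radius - d_lat) / (sigma_b * sqrt(2))))
        keep <- which(w > 1e-4)
        if (!length(keep)) next
        mu <- mu_a_rel(v, optical, i) * e_ratio[i]
        sig_z <- max(v$radius / 2, dz)
        for (j in keep) {
          zj <- pts[j, 3]
          i0 <- max(1L, floor((zj - 4 * sig_z) / dz) + 1L)
          i1 <- min(n_win, ceiling((zj + 4 * sig_z) / dz) + 1L)
          if (i0 > i1) next
          zz <- z[i0:i1]
          A[i0:i1] <- A[i0:i1] +
            mu * w[j] * (v$radius / 25e-6) * (ds / 25e-6) *
            exp(-(zz - zj)^2 / (2 * sig_z^2))
        }
      }
    } else {
      for (e in phantom$edges) {
        s <- if (e$orientation == "x") pose[1] else pose[2]
        fw <- beam_fwhm(optical, e$depth - zfoc)
        sigma_b <- fw / (2 * sqrt(2 * log(2)))
        cover <- 0.5 * (1 + pracma::erf((s - e$position) / (sigma_b * sqrt(2))))
        sig_z <- max(10e-6, dz)
        A <- A + e$strength * e_ratio[i] * cover *
          exp(-(z - e$depth)^2 / (2 * sig_z^2))
      }
    }
    if (all(A == 0)) numeric(n_win) else conv_centered(A, tmpl) * amp_scale
  })
  samples <- c(windows[[1]], windows[[2]])
  if (noise_rms > 0) {
    samples <- with_seed_or_current(rng_seed,
      samples + stats::rnorm(length(samples), 0, noise_rms))
  }
  time_trace(samples, sample_rate, "Pa")
}

#' Rasterize phantom ground truth onto a scan grid
#'
#' Projects the vasculature phantom onto the lateral plane of a scan grid,
#' producing the ground-truth vessel mask, sO2 map and depth map (nearest
#' vessel wins where vessels overlap; deeper structure is shadowed by
#' shallower). Used as the reference for validating segmentation and sO2
#' recovery.
#'
#' @param phantom a vasculature `phantom`.
#' @param xs,ys pixel-center coordinates (m) of the grid columns and rows.
#' @return A list with matrices `mask` (logical), `so2`, `depth` (NA off-mask),
#'   each `length(ys)` x `length(xs)`.
#' @export
rasterize_phantom <- function(phantom, xs, ys) {
  stopifnot(phantom$kind == "vasculature")
  nx <- length(xs); ny <- length(ys)
  mask <- matrix(FALSE, ny, nx)
  so2 <- matrix(NA_real_, ny, nx)
  depth <- matrix(NA_real_, ny, nx)
  zbest <- matrix(Inf, ny, nx)
  px <- matrix(xs, ny, nx, byrow = TRUE)
  py <- matrix(ys, ny, nx)
  for (v in phantom$vessels) {
    pts <- resample_polyline(v$centerline, max(v$radius / 2, 5e-6))
    for (j in seq_len(nrow(pts))) {
      d2 <- (px - pts[j, 1])^2 + (py - pts[j, 2])^2
      hit <- d2 <= v$radius^2 & pts[j, 3] < zbest
      if (any(hit)) {
        mask[hit] <- TRUE
        so2[hit] <- v$so2
        depth[hit] <- pts[j, 3]
        zbest[hit] <- pts[j, 3]
      }
    }
  }
  list(mask = mask, so2 = so2, depth = depth)
}
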