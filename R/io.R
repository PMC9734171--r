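## Constructors reachable from config files, keyed by the `type` field.
.config_constructors <- c(
  sensor_spec = "sensor_spec",
  demod_config = "demod_config",
  hydrophone_spec = "hydrophone_spec",
  optical_model = "optical_model",
  scan_geometry = "scan_geometry"
)

#' Write configuration objects to a YAML file
#'
#' Serializes any mix of [sensor_spec()], [demod_config()],
#' [hydrophone_spec()], [optical_model()] and [scan_geometry()] objects as
#' named YAML blocks tagged with their type, so [read_config()] can rebuild
#' them through the validating constructors.
#'
#' @param objects named list of configuration objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(objects, path) {
  stopifnot(is.list(objects), !is.null(names(objects)))
  blocks <- lapply(objects, function(obj) {
    type <- class(obj)[1]
    if (!type %in% names(.config_constructors))
      stop("cannot serialize objects of class ", type)
    c(list(type = type), unclass(obj))
  })
  yaml::write_yaml(blocks, path, precision = 15L)
  invisible(path)
}

#' Read configuration objects from a YAML file
#'
#' @param path a YAML file written by [write_config()] (or hand-authored with
#'   the same `type:` tags).
#' @return Named list of reconstructed, validated configuration objects.
#' @export
read_config <- function(path) {
  blocks <- yaml::read_yaml(path)
  lapply(blocks, function(b) {
    type <- b$type
    if (is.null(type) || !type %in% names(.config_constructors))
      stop("config block without a recognized type tag")
    b$type <- NULL
    ctor <- get(.config_constructors[[type]], mode = "function")
    args <- b[names(b) %in% names(formals(ctor))]
    args <- lapply(args, function(v) if (is.list(v)) unlist(v) else v)
    do.call(ctor, args)
  })
}

#' Export a trace to headered CSV
#'
#' Plain-text exchange format: comment header lines carry `sample_rate`,
#' `unit` and `t0`; the body is a single `value` column.
#'
#' @param trace a [time_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "time_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample_rate: %.17g", trace$sample_rate),
    sprintf("# unit: %s", trace$unit),
    sprintf("# t0: %.17g", trace$t0),
    "value"
  ), con)
  writeLines(sprintf("%.17g", Re(trace$samples)), con)
  invisible(path)
}

#' Import a trace from headered CSV
#'
#' @param path a file written by [write_trace_csv()].
#' @return A [time_trace()].
#' @export
read_trace_csv <- function(path) {
  header <- readLines(path, n = 3L)
  get_field <- function(key) {
    line <- header[startsWith(header, paste0("# ", key, ":"))]
    if (!length(line)) stop("missing header field: ", key)
    trimws(sub(paste0("# ", key, ":"), "", line))
  }
  vals <- utils::read.csv(path, comment.char = "#")$value
  time_trace(vals, as.numeric(get_field("sample_rate")),
             get_field("unit"), as.numeric(get_field("t0")))
}

#' Export a spectral density (or NEPD spectrum) to CSV
#'
#' @param sd a [spectral_density()] or `nepd_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(sd, path) {
  df <- if (inherits(sd, "nepd_spectrum")) {
    data.frame(freq_hz = sd$freqs, value = sd$nepd, unit = "Pa Hz^-1/2")
  } else {
    as.data.frame(sd)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write functional maps as a multi-page TIFF plus CSV metadata
#'
#' One page per map (C_Hb, depth, sO2, mask), each affinely rescaled into the
#' TIFF [0, 1] range; the per-page offset/scale are written to a CSV sidecar
#' (`<path>.meta.csv`) so [read_maps_tiff()] restores physical units. Off-mask
#' pixels (NA) are stored as 0 and restored from the mask page.
#'
#' @param maps a [functional_maps()].
#' @param path output TIFF path.
#' @param meta_csv metadata sidecar path (default `<path>.meta.csv`).
#' @return `path`, invisibly.
#' @export
write_maps_tiff <- function(maps, path, meta_csv = paste0(path, ".meta.csv")) {
  stopifnot(inherits(maps, "functional_maps"))
  enc <- function(m) {
    rng <- suppressWarnings(range(m, na.rm = TRUE))
    if (!is.finite(rng[1])) rng <- c(0, 1)
    if (diff(rng) == 0) rng[2] <- rng[1] + 1
    x <- (m - rng[1]) / diff(rng)
    x[is.na(x)] <- 0
    list(page = x, min = rng[1], max = rng[2])
  }
  e <- lapply(list(maps$chb, maps$depth, maps$so2), enc)
  pages <- c(lapply(e, `[[`, "page"), list(maps$mask * 1.0))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  utils::write.csv(data.frame(
    map = c("chb", "depth", "so2", "mask"),
    min = c(vapply(e, `[[`, 0, "min"), 0),
    max = c(vapply(e, `[[`, 0, "max"), 1)
  ), meta_csv, row.names = FALSE)
  invisible(path)
}

#' Read functional maps from a multi-page TIFF
#'
#' @param path a file written by [write_maps_tiff()].
#' @param geometry the [scan_geometry()] to attach.
#' @param meta_csv metadata sidecar path (default `<path>.meta.csv`).
#' @return A [functional_maps()] object.
#' @export
read_maps_tiff <- function(path, geometry, meta_csv = paste0(path, ".meta.csv")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == 4L)
  meta <- utils::read.csv(meta_csv)
  mask <- pages[[4]] > 0.5
  dec <- function(i, na_off_mask = TRUE) {
    m <- pages[[i]] * (meta$max[i] - meta$min[i]) + meta$min[i]
    if (na_off_mask) m[!mask] <- NA_real_
    m
  }
  functional_maps(dec(1, na_off_mask = FALSE), dec(2), dec(3), mask, geometry)
}

#' Plain-text calibration report
#'
#' Structured summary of a calibration run: sensor parameters, in-band
#' response and noise levels, and the band-integrated r.m.s. NEP.
#'
#' @param spec the [sensor_spec()].
#' @param nepd an `nepd_spectrum`.
#' @param band reporting band (Hz).
#' @param path optional file to write to.
#' @return The report lines, invisibly if `path` is given.
#' @export
calibration_report <- function(spec, nepd, band = nepd$band, path = NULL) {
  inb <- nepd$freqs >= band[1] & nepd$freqs <= band[2] & !is.na(nepd$nepd)
  lines <- c(
    "== laser ultrasound sensor calibration ==",
    sprintf("lasing frequency     : %.6g THz", spec$omega0 / (2 * pi * 1e12)),
    sprintf("beat frequency       : %.4g GHz", spec$omega_b / (2 * pi * 1e9)),
    sprintf("Sm baseline          : %.3g /Pa (resonance %.3g MHz, Q %.3g)",
            spec$Sm_base, spec$f_res / 1e6, spec$Q_res),
    sprintf("band                 : %.3g - %.3g MHz", band[1] / 1e6, band[2] / 1e6),
    sprintf("median NEPD in band  : %.4g Pa Hz^-1/2",
            stats::median(nepd$nepd[inb])),
    sprintf("r.m.s. NEP in band   : %.4g Pa", rms_nep(nepd, band))
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
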