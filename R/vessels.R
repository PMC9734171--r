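## 8-connected labelling of a logical matrix via graph components.
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  id <- integer(length(mask)); id[idx] <- seq_along(idx)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  edges <- list()
  rc_r <- ((idx - 1L) %% nr) + 1L
  rc_c <- ((idx - 1L) %/% nr) + 1L
  for (s in shifts) {
    r2 <- rc_r + s[1]; c2 <- rc_c + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[j]
    if (any(hit)) {
      edges[[length(edges) + 1L]] <-
        cbind(id[idx[ok][hit]], id[j[hit]])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    el <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(el))
  }
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

## Count of 8-neighbours that are TRUE, per pixel (zero-padded borders).
neighbor_count8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m * 1L
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    acc <- acc + p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  acc
}

## Zhang-Suen topological thinning of a logical matrix to 1-px centerlines.
thin_zhang_suen <- function(mask) {
  m <- mask * 1L
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- matrix(0L, nr + 2L, nc + 2L)
      p[2:(nr + 1L), 2:(nc + 1L)] <- m
      sh <- function(dr, dc) p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
      P2 <- sh(-1L, 0L); P3 <- sh(-1L, 1L); P4 <- sh(0L, 1L); P5 <- sh(1L, 1L)
      P6 <- sh(1L, 0L); P7 <- sh(1L, -1L); P8 <- sh(0L, -1L); P9 <- sh(-1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) +
        (P4 == 0L & P5 == 1L) + (P5 == 0L & P6 == 1L) +
        (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
        (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
      if (step == 1) {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      } else {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

#' Segment vessels from a hemoglobin-concentration map
#'
#' Global thresholding (automatic bimodal split by Otsu's method, or a fixed
#' value) followed by small-object removal on 8-connected components.
#'
#' @param chb_map numeric matrix of C_Hb amplitudes.
#' @param threshold fixed threshold value; `NULL` (default) uses Otsu's
#'   bimodal split on the normalized image.
#' @param min_area minimum component area kept, in pixels.
#' @return A logical matrix (TRUE = vessel). A constant image yields an empty
#'   mask.
#' @export
segment_vessels <- function(chb_map, threshold = NULL, min_area = 9L) {
  stopifnot(is.matrix(chb_map))
  rng <- range(chb_map, na.rm = TRUE)
  if (!is.finite(rng[1]) || diff(rng) == 0)
    return(matrix(FALSE, nrow(chb_map), ncol(chb_map)))
  if (is.null(threshold)) {
    norm <- (chb_map - rng[1]) / diff(rng)
    norm[is.na(norm)] <- 0
    th_norm <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    threshold <- rng[1] + th_norm * diff(rng)
  }
  mask <- !is.na(chb_map) & chb_map > threshold
  if (min_area > 1L && any(mask)) {
    lab <- label8(mask)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < min_area)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  mask
}

#' Skeletonize a vessel mask and split it into per-vessel records
#'
#' Topological (Zhang-Suen) thinning reduces the mask to one-pixel
#' centerlines, which are split into branches at junction pixels (skeleton
#' pixels with three or more skeleton neighbours, 8-connectivity); branches
#' shorter than `min_branch` pixels are dropped. Per branch, the vessel
#' diameter comes from the mean Euclidean distance-transform value `d` along
#' the centerline as `2 d - 1` pixels (the distance transform counts to the
#' first background pixel center, half a pixel beyond the vessel boundary on
#' each side), and `C_Hb` / sO2 are averaged over centerline pixels.
#'
#' @param mask logical vessel mask.
#' @param chb_map,so2_map optional matrices sampled along centerlines.
#' @param min_branch minimum branch length kept (pixels).
#' @param pixel_size physical pixel pitch (m/px) used to scale diameters.
#' @return A list with `records` (data.frame: `id`, `n_pixels`, `diameter`,
#'   `mean_chb`, `mean_so2`), `skeleton` (logical matrix) and `labels`
#'   (integer matrix of branch ids). An empty mask gives zero records.
#' @export
skeletonize_and_split <- function(mask, chb_map = NULL, so2_map = NULL,
                                  min_branch = 3L, pixel_size = 1) {
  stopifnot(is.matrix(mask))
  empty <- list(
    records = data.frame(id = integer(), n_pixels = integer(),
                         diameter = numeric(), mean_chb = numeric(),
                         mean_so2 = numeric()),
    skeleton = matrix(FALSE, nrow(mask), ncol(mask)),
    labels = matrix(0L, nrow(mask), ncol(mask))
  )
  if (!any(mask)) return(empty)
  skel <- thin_zhang_suen(mask)
  if (!any(skel)) return(empty)
  dist <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask)))
  nb <- neighbor_count8(skel)
  junction <- skel & nb >= 3L
  branches <- skel & !junction
  lab <- label8(branches)
  ids <- sort(unique(lab[lab > 0L]))
  rows <- lapply(ids, function(i) {
    px <- which(lab == i)
    if (length(px) < min_branch) return(NULL)
    data.frame(
      id = i, n_pixels = length(px),
      diameter = (2 * mean(dist[px]) - 1) * pixel_size,
      mean_chb = if (is.null(chb_map)) NA_real_ else mean(chb_map[px], na.rm = TRUE),
      mean_so2 = if (is.null(so2_map)) NA_real_ else mean(so2_map[px], na.rm = TRUE)
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  records <- if (length(rows)) do.call(rbind, rows) else empty$records
  keep_ids <- records$id
  lab[!(lab %in% keep_ids)] <- 0L
  records$id <- seq_len(nrow(records))
  list(records = records, skeleton = skel, labels = lab)
}

#' Dice overlap coefficient of two masks
#'
#' @param a,b logical matrices of equal shape.
#' @return `2 |a & b| / (|a| + |b|)`; 1 for two empty masks.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Time-lapse vessel statistics over a fixed region of interest
#'
#' For each time point: segments vessels from the C_Hb map, skeletonizes and
#' counts them, and reports the vessel density (vessel-pixel fraction of the
#' ROI), the mean per-vessel C_Hb and sO2 (averages of centerline values) and
#' the sO2 distribution over mask pixels. Each metric's relative change versus
#' the first (baseline) time point is attached.
#'
#' @param maps_list list of [functional_maps()] (or lists with `chb` and `so2`
#'   matrices), congruent shapes, baseline first.
#' @param roi optional `c(row1, row2, col1, col2)` crop applied to every map.
#' @param timepoints numeric labels (e.g. minutes), defaults to
#'   `0, 30, 60, ...`.
#' @param so2_breaks histogram bin edges for the sO2 distribution.
#' @param threshold,min_area forwarded to [segment_vessels()].
#' @return A list with `summary` (data.frame per timepoint: `timepoint`,
#'   `vessel_count`, `vessel_density`, `mean_chb`, `mean_so2`),
#'   `so2_histograms` (matrix, one row per timepoint, rows sum to 1) and
#'   `rel_change` (same columns as summary, fractional change vs baseline).
#' @export
timelapse_metrics <- function(maps_list, roi = NULL, timepoints = NULL,
                              so2_breaks = seq(0, 1, by = 0.1),
                              threshold = NULL, min_area = 9L) {
  stopifnot(length(maps_list) >= 1L)
  if (is.null(timepoints)) timepoints <- 30 * (seq_along(maps_list) - 1L)
  crop <- function(m) {
    if (is.null(roi)) m else m[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  }
  dims0 <- dim(crop(maps_list[[1]]$chb))
  rows <- list(); hists <- list()
  for (i in seq_along(maps_list)) {
    chb <- crop(maps_list[[i]]$chb)
    so2 <- crop(maps_list[[i]]$so2)
    if (!identical(dim(chb), dims0))
      stop("ROI shapes differ between timepoints")
    mask <- segment_vessels(chb, threshold = threshold, min_area = min_area)
    sk <- skeletonize_and_split(mask, chb_map = chb, so2_map = so2)
    so2_on <- so2[mask]
    so2_on <- so2_on[!is.na(so2_on)]
    h <- if (length(so2_on)) {
      cnt <- graphics::hist(pmin(pmax(so2_on, min(so2_breaks)),
                                 max(so2_breaks)),
                            breaks = so2_breaks, plot = FALSE)$counts
      cnt / sum(cnt)
    } else rep(0, length(so2_breaks) - 1L)
    rows[[i]] <- data.frame(
      timepoint = timepoints[i],
      vessel_count = nrow(sk$records),
      vessel_density = mean(mask),
      mean_chb = if (nrow(sk$records)) mean(sk$records$mean_chb) else NA_real_,
      mean_so2 = if (nrow(sk$records)) mean(sk$records$mean_so2) else NA_real_
    )
    hists[[i]] <- h
  }
  summary <- do.call(rbind, rows)
  base <- summary[1, ]
  rel <- summary
  for (col in c("vessel_count", "vessel_density", "mean_chb", "mean_so2")) {
    rel[[col]] <- (summary[[col]] - base[[col]]) / base[[col]]
  }
  list(summary = summary, so2_histograms = do.call(rbind, hists),
       rel_change = rel)
}

#' Repeated-measures significance test across timepoints
#'
#' Smoke-level delegation to standard routines: one-way repeated-measures
#' ANOVA (`stats::aov` with a subject error stratum) plus Dunnett-type
#' contrasts against baseline via `multcomp` when available.
#'
#' @param values matrix of a metric, subjects in rows, timepoints in columns.
#' @param timepoints column labels.
#' @return A list with `p_anova` and (if multcomp is installed)
#'   `p_dunnett` (one p-value per non-baseline timepoint).
#' @export
timelapse_anova <- function(values, timepoints = seq_len(ncol(values))) {
  stopifnot(is.matrix(values), nrow(values) >= 2L, ncol(values) >= 2L)
  df <- data.frame(
    value = as.vector(values),
    time = factor(rep(timepoints, each = nrow(values))),
    subject = factor(rep(seq_len(nrow(values)), times = ncol(values)))
  )
  fit <- stats::aov(value ~ time + Error(subject), data = df)
  s <- summary(fit)
  p_anova <- tryCatch(s[["Error: Within"]][[1]][["Pr(>F)"]][1],
                      error = function(e) NA_real_)
  out <- list(p_anova = p_anova)
  if (requireNamespace("multcomp", quietly = TRUE)) {
    fit2 <- stats::aov(value ~ time + subject, data = df)
    gl <- multcomp::glht(fit2, linfct = multcomp::mcp(time = "Dunnett"))
    out$p_dunnett <- as.numeric(summary(gl)$test$pvalues)
  }
  out
}
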