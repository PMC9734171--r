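# synthetic two-level map: background level plus rectangles of vessel signal
two_level_map <- function(nr = 60, nc = 60, bars = list(c(20, 26, 8, 52)),
                          lo = 0.1, hi = 1) {
  m <- matrix(lo, nr, nc)
  truth <- matrix(FALSE, nr, nc)
  for (b in bars) {
    m[b[1]:b[2], b[3]:b[4]] <- hi
    truth[b[1]:b[2], b[3]:b[4]] <- TRUE
  }
  list(map = m, truth = truth)
}

test_that("vessel segmentation thresholds bimodal images and drops specks", {
  # uniform background -> empty mask
  expect_false(any(segment_vessels(matrix(0.3, 40, 40))))
  # clean two-level image -> exact ground truth
  tl <- two_level_map()
  expect_identical(segment_vessels(tl$map), tl$truth)
  # small objects below min_area are removed, larger ones survive
  m <- matrix(0, 50, 50)
  m[10:11, 10:11] <- 1          # 4 px speck
  m[30:36, 30:36] <- 1          # 49 px block
  mask <- segment_vessels(m, threshold = 0.5, min_area = 9)
  expect_equal(sum(mask), 49)
  expect_false(mask[10, 10])
})

test_that("skeletonization splits branches and measures bar width within a pixel", {
  # straight bar of width 7 -> a single record with diameter 7 +/- 1 px
  mask <- matrix(FALSE, 40, 80)
  mask[17:23, 10:70] <- TRUE
  sk <- skeletonize_and_split(mask)
  expect_equal(nrow(sk$records), 1)
  expect_equal(sk$records$diameter, 7, tolerance = 1 / 7)
  # skeleton runs along the bar center row
  rows <- ((which(sk$skeleton) - 1) %% 40) + 1
  expect_true(all(abs(rows - 20) <= 1))
  # Y junction -> three branch records
  m2 <- matrix(FALSE, 60, 60)
  for (i in 0:25) m2[30 + 0:2, 5 + i] <- TRUE
  for (i in 0:20) {
    m2[30 - i + 0:2, 30 + i] <- TRUE
    m2[30 + i + 0:2, 30 + i] <- TRUE
  }
  expect_equal(nrow(skeletonize_and_split(m2)$records), 3)
  # empty mask -> no records
  expect_equal(nrow(skeletonize_and_split(matrix(FALSE, 10, 10))$records), 0)
})

test_that("per-branch means sample centerline values and scale with pixel size", {
  tl <- two_level_map(bars = list(c(20, 26, 8, 52)))
  chb <- tl$map
  so2 <- matrix(NA_real_, 60, 60)
  so2[tl$truth] <- 0.8
  sk <- skeletonize_and_split(tl$truth, chb_map = chb, so2_map = so2,
                              pixel_size = 5e-6)
  expect_equal(sk$records$mean_chb, 1)
  expect_equal(sk$records$mean_so2, 0.8)
  expect_equal(sk$records$diameter, 7 * 5e-6, tolerance = 1 / 7)
})

test_that("skeleton count is invariant under intensity scaling and monotone in vessels", {
  tl1 <- two_level_map(bars = list(c(10, 14, 5, 55)))
  tl2 <- two_level_map(bars = list(c(10, 14, 5, 55), c(40, 44, 5, 55)))
  count <- function(map) {
    mask <- segment_vessels(map)
    nrow(skeletonize_and_split(mask)$records)
  }
  expect_equal(count(tl1$map), count(tl1$map * 7.3))
  expect_gte(count(tl2$map), count(tl1$map))
  expect_gte(mean(segment_vessels(tl2$map)), mean(segment_vessels(tl1$map)))
})

test_that("time-lapse metrics report densities, histograms and baseline changes", {
  tl1 <- two_level_map(bars = list(c(10, 14, 5, 55)))
  so2_a <- matrix(NA_real_, 60, 60); so2_a[tl1$truth] <- 0.62
  m1 <- list(chb = tl1$map, so2 = so2_a)
  # identical maps at two timepoints -> zero change everywhere
  out <- timelapse_metrics(list(m1, m1), timepoints = c(0, 30))
  expect_equal(out$rel_change$vessel_density[2], 0)
  expect_equal(out$rel_change$mean_so2[2], 0)
  expect_equal(out$rel_change$vessel_count[2], 0)
  # histograms normalized
  expect_equal(rowSums(out$so2_histograms), c(1, 1))
  # +0.07 shift of all sO2 values moves the mean by exactly 0.07
  so2_b <- so2_a + 0.07
  m2 <- list(chb = tl1$map, so2 = so2_b)
  out2 <- timelapse_metrics(list(m1, m2), timepoints = c(0, 30))
  expect_equal(out2$summary$mean_so2[2] - out2$summary$mean_so2[1], 0.07)
  # histogram mass moves to the right bin
  expect_equal(which(out2$so2_histograms[1, ] > 0), 7)   # 0.6-0.7
  expect_equal(which(out2$so2_histograms[2, ] > 0), 7)   # 0.69 stays in bin 7
  # a programmed density increase is recovered
  tl3 <- two_level_map(bars = list(c(10, 14, 5, 55), c(40, 42, 5, 55)))
  m3 <- list(chb = tl3$map, so2 = so2_a)
  out3 <- timelapse_metrics(list(m1, m3), timepoints = c(0, 30))
  truth_change <- (sum(tl3$truth) - sum(tl1$truth)) / sum(tl1$truth)
  expect_equal(out3$rel_change$vessel_density[2], truth_change,
               tolerance = 0.02)
  # mismatched ROI shapes are refused
  bad <- list(chb = tl1$map[1:30, ], so2 = so2_a[1:30, ])
  expect_error(timelapse_metrics(list(m1, bad)), "shapes")
})

test_that("repeated-measures significance testing yields valid p-values", {
  withr::with_seed(11, {
    vals <- matrix(rnorm(12, mean = rep(c(0.6, 0.63, 0.66, 0.65), each = 3),
                         sd = 0.01),
                   nrow = 3)
  })
  out <- timelapse_anova(vals, timepoints = c(0, 30, 60, 90))
  expect_gte(out$p_anova, 0)
  expect_lte(out$p_anova, 1)
  if (!is.null(out$p_dunnett)) {
    expect_true(all(out$p_dunnett >= 0 & out$p_dunnett <= 1))
    expect_length(out$p_dunnett, 3)
  }
})

test_that("dice coefficient behaves at the boundaries", {
  a <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, !a), 0)
  empty <- matrix(FALSE, 2, 2)
  expect_equal(dice_coefficient(empty, empty), 1)
})
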