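toy_mono_section <- function(vals, mono_px = 10000L) {
  # monocular region of exactly `mono_px` pixels filled column-major with vals
  nr <- 120L
  nc <- 120L
  img <- matrix(0, nr, nc)
  mask <- matrix(TRUE, nr, nc)
  mono <- matrix(FALSE, nr, nc)
  mono[seq_len(mono_px)] <- TRUE
  img[seq_len(mono_px)] <- vals
  lm <- list(dm_tip = c(1, 1), vl_tip = c(nr, 1), outer_arc = cbind(seq_len(nr), 1))
  section_image(img, mask, lm, monocular_region = mono)
}

test_that("Mc averages the first 10,000 monocular pixels in raster order", {
  expect_equal(compute_Mc(toy_mono_section(rep(12, 10000))), 12)
  expect_equal(compute_Mc(toy_mono_section(rep(c(0, 20), each = 5000))), 10)
  # extra monocular pixels beyond the subsample do not contribute
  big <- toy_mono_section(c(rep(5, 10000), rep(1000, 2000)), mono_px = 12000L)
  expect_equal(compute_Mc(big), 5)
  expect_error(compute_Mc(toy_mono_section(rep(1, 500), mono_px = 500L)),
               "monocular segment")
  expect_error(threshold_Tc(0), "positive")
  expect_equal(threshold_Tc(10, 0.5), 5)
})

test_that("gap extraction excludes contour-connected regions by flood fill", {
  # 10x10 dLGN, 2x2 interior hole, 1-px rim notch touching the contour
  mask <- matrix(FALSE, 14, 14); mask[3:12, 3:12] <- TRUE
  img <- matrix(0, 14, 14); img[mask] <- 10
  img[6:7, 6:7] <- 0          # the gap
  img[3, 7] <- 0              # the notch, on the boundary row
  lm <- list(dm_tip = c(3, 3), vl_tip = c(12, 3), outer_arc = cbind(3:12, 3))
  sec <- section_image(img, mask, lm)
  res <- gap_size(sec, 5)
  expect_true(res$valid)
  expect_equal(res$gap_area_um2, 4)
  expect_equal(res$gap_fraction_pct, 4)
  # agreement with the brute-force BFS oracle
  expect_equal(res$gap_area_um2, sum(bfs_gap(mask, mask & img < 5)))
})

test_that("gap flood fill matches the BFS oracle on random masks", {
  set.seed(99)
  for (i in 1:50) {
    mask <- matrix(FALSE, 20, 20); mask[3:18, 3:18] <- TRUE
    img <- matrix(round(runif(400, 0, 10)), 20, 20)
    lm <- list(dm_tip = c(3, 3), vl_tip = c(18, 3), outer_arc = cbind(3:18, 3))
    sec <- section_image(img, mask, lm)
    res <- gap_size(sec, 5, max_rim_depth = 20L)  # depth gate off: pure flood fill
    expect_equal(res$gap_area_um2, sum(bfs_gap(mask, mask & img < 5)),
                 label = sprintf("grid %d", i))
  }
})

test_that("gap, contour-connected and supra-threshold pixels partition the dLGN", {
  set.seed(7)
  mask <- matrix(FALSE, 30, 30); mask[4:27, 4:27] <- TRUE
  img <- matrix(round(runif(900, 0, 10)), 30, 30)
  lm <- list(dm_tip = c(4, 4), vl_tip = c(27, 4), outer_arc = cbind(4:27, 4))
  sec <- section_image(img, mask, lm)
  Tc <- 5
  res <- gap_size(sec, Tc, max_rim_depth = 30L)
  sub <- mask & img < Tc
  n_gap <- res$gap_area_um2
  n_contour_connected <- sum(sub) - n_gap
  n_supra <- sum(mask & img >= Tc)
  expect_equal(n_gap + n_contour_connected + n_supra, sum(mask))
})

test_that("gap size is monotone non-decreasing in Tc until validity flips", {
  ms <- phantom_fixture("contra")
  idx <- select_analysis_section(ms$series)
  sec <- subtract_background(ms$series$sections[[idx]],
                             estimate_background(ms$series$sections[[idx]]))
  tcs <- seq(200, 2400, by = 200)
  res <- lapply(tcs, function(tc) gap_size(sec, tc))
  valid <- vapply(res, function(r) r$valid, logical(1))
  areas <- vapply(res, function(r) r$gap_area_um2, numeric(1))
  expect_true(all(diff(areas[valid]) >= 0))
  # validity can only flip valid -> invalid as the threshold grows
  expect_true(all(diff(as.integer(valid)) <= 0))
})

test_that("a fully labelled dLGN has a zero, valid gap", {
  mask <- matrix(FALSE, 12, 12); mask[2:11, 2:11] <- TRUE
  img <- matrix(0, 12, 12); img[mask] <- 10
  lm <- list(dm_tip = c(2, 2), vl_tip = c(11, 2), outer_arc = cbind(2:11, 2))
  res <- gap_size(section_image(img, mask, lm), 5)
  expect_true(res$valid)
  expect_equal(res$gap_fraction_pct, 0)
})

test_that("a phantom gap opened to the contour invalidates the section", {
  sp <- phantom_spec(gap_fraction = 0.1, gap_touches_contour = TRUE)
  ms <- make_series(sp)
  idx <- select_analysis_section(ms$series)
  sec <- subtract_background(ms$series$sections[[idx]],
                             estimate_background(ms$series$sections[[idx]]))
  res <- gap_size(sec, threshold_Tc(compute_Mc(sec)))
  expect_false(res$valid)
  expect_true(is.na(res$gap_fraction_pct))
})

test_that("intensity profile normalizes by the trailing monocular segment", {
  # uniform image: every bin is exactly 1
  img <- matrix(8, 320, 320)
  mask <- matrix(FALSE, 320, 320); mask[31:290, 100:200] <- TRUE
  lm <- list(dm_tip = c(31, 150), vl_tip = c(290, 150),
             outer_arc = cbind(31, 100:200))
  sec <- section_image(img, mask, lm)
  pr <- intensity_profile(sec)
  expect_true(all(abs(pr$normalized_intensity - 1) < 1e-12))
  expect_equal(pr$distance_um[2] - pr$distance_um[1], 1)
  # linear ramp doubling over the strip: first bin < 1 < last bin
  img2 <- matrix(rep(seq(100, 200, length.out = 320), 320), 320, 320)
  pr2 <- intensity_profile(section_image(img2, mask, lm))
  expect_lt(pr2$normalized_intensity[1], 1)
  expect_gt(pr2$normalized_intensity[nrow(pr2)], 1)
  expect_true(all(diff(pr2$normalized_intensity) > 0))
  # strip shorter than the 200-bin normalization segment
  lm_short <- list(dm_tip = c(31, 150), vl_tip = c(130, 150),
                   outer_arc = cbind(31, 100:200))
  expect_error(intensity_profile(section_image(img, mask, lm_short)),
               "at least 200")
})

test_that("profile is invariant to uniform intensity scaling", {
  ms <- phantom_fixture("contra")
  idx <- select_analysis_section(ms$series)
  sec <- subtract_background(ms$series$sections[[idx]],
                             estimate_background(ms$series$sections[[idx]]))
  pr1 <- intensity_profile(sec)
  sec2 <- sec; sec2$intensity <- sec$intensity * 3.7
  pr2 <- intensity_profile(sec2)
  expect_equal(pr2$normalized_intensity, pr1$normalized_intensity,
               tolerance = 1e-12)
})

test_that("profile dips toward background level where it crosses the gap", {
  # place the gap centre on the DM-VL chord so the strip traverses it
  sp <- phantom_spec(gap_fraction = 0.10, gap_theta = 42.8 * pi / 180)
  ms <- make_series(sp)
  idx <- select_analysis_section(ms$series)
  sec <- subtract_background(ms$series$sections[[idx]],
                             estimate_background(ms$series$sections[[idx]]))
  pr <- intensity_profile(sec)
  # bins inside the gap fall to ~ background/plateau = 0; plateau bins sit
  # near the monocular normalization level
  expect_lt(min(pr$normalized_intensity), 0.1)
  expect_equal(max(pr$normalized_intensity), 1, tolerance = 0.1)
})

test_that("VGLUT1 profile subtracts the no-primary control and normalizes by the strip mean", {
  # bins [2,2,4,4] with zero background -> [2/3, 2/3, 4/3, 4/3]
  img <- matrix(rep(c(2, 2, 4, 4), times = 41), 4, 41)
  lm <- list(dm_tip = c(1, 21), vl_tip = c(4, 21), outer_arc = cbind(1, 1:41))
  mask <- matrix(TRUE, 4, 41)
  sec <- section_image(img, mask, lm)
  pr <- vglut1_profile(sec, 0, width = 41L)
  expect_equal(pr$normalized_intensity, c(2, 2, 4, 4) / 3)
  # uniform image: all bins 1
  u <- section_image(matrix(6, 4, 41), mask, lm)
  expect_true(all(abs(vglut1_profile(u, 0, width = 41L)$normalized_intensity - 1) < 1e-12))
  # background equal to the uniform signal: zero divisor
  expect_error(vglut1_profile(u, 6, width = 41L), "zero")
})
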