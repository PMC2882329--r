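make_area_series <- function(areas) {
  # one section per requested mask pixel count, constant intensity
  sections <- lapply(areas, function(a) {
    mask <- matrix(FALSE, 40, 40)
    mask[cbind(((seq_len(a) - 1) %% 40) + 1, ((seq_len(a) - 1) %/% 40) + 1)] <- TRUE
    lm <- list(dm_tip = c(1, 1), vl_tip = c(40, 1),
               outer_arc = cbind(seq_len(40), 1))
    section_image(matrix(1, 40, 40), mask, lm)
  })
  section_series(sections)
}

test_that("analysis section sits two 50-um steps rostral to the area argmax", {
  expect_equal(select_analysis_section(make_area_series(c(100, 200, 300, 250, 150))), 1L)
  expect_error(select_analysis_section(make_area_series(c(300, 200, 100))),
               "rostral")
  # area ties break toward the more rostral section, which here leaves no
  # section 100 um rostral
  expect_error(select_analysis_section(make_area_series(c(100, 300, 300, 200, 100))),
               "rostral")
  expect_equal(select_analysis_section(make_area_series(c(1, 2, 100, 300, 300))), 2L)
})

test_that("analysis-section choice ignores uniform intensity rescaling", {
  s <- make_area_series(c(100, 200, 300, 250, 150))
  s2 <- s
  s2$sections <- lapply(s$sections, function(x) { x$intensity <- x$intensity * 37; x })
  expect_equal(select_analysis_section(s2), select_analysis_section(s))
})

test_that("background estimation averages exactly 40,000 off-nucleus pixels", {
  img <- matrix(7, 320, 320)
  mask <- matrix(FALSE, 320, 320); mask[11:50, 251:300] <- TRUE
  lm <- list(dm_tip = c(11, 251), vl_tip = c(50, 251),
             outer_arc = cbind(11, 251:300))
  sec <- section_image(img, mask, lm)
  expect_equal(estimate_background(sec), 7)
  # default placement: 200x200 square 10 px down-left of the mask bounding box
  reg <- default_background_region(sec)
  expect_equal(unname(reg[3] * reg[4]), 40000)
  # half 0 / half 10 region
  img2 <- img; img2[61:260, 42:241] <- rep(c(0, 10), each = 20000)
  sec2 <- section_image(img2, mask, lm)
  expect_equal(estimate_background(sec2, region = c(61, 42, 200, 200)), 5)
  # misplacements are rejected with distinct diagnostics
  expect_error(estimate_background(sec, region = c(11, 101, 200, 200)), "overlaps")
  expect_error(estimate_background(sec, region = c(200, 200, 200, 200)), "bounds")
  expect_error(estimate_background(sec, region = c(61, 42, 100, 100)), "40,000")
})

test_that("background subtraction clamps at zero and is monotone", {
  img <- matrix(c(5, 7, 9, 0), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  lm <- list(dm_tip = c(1, 1), vl_tip = c(2, 1), outer_arc = cbind(1:2, 1))
  sec <- section_image(img, mask, lm)
  expect_equal(subtract_background(sec, 0)$intensity, img)
  s7 <- subtract_background(sec, 7)
  expect_equal(s7$intensity, matrix(c(0, 0, 2, 0), 2, 2))
  expect_true(all(s7$intensity <= img))
  # idempotent once nothing is left to clamp differently
  expect_equal(subtract_background(subtract_background(sec, 0), 0)$intensity, img)
  expect_error(subtract_background(sec, -1), ">= 0")
})

test_that("dLGN area is the mask pixel count times the pixel footprint", {
  mask <- matrix(FALSE, 20, 20); mask[1:10, 1:10] <- TRUE
  lm <- list(dm_tip = c(1, 1), vl_tip = c(10, 1), outer_arc = cbind(1:10, 1))
  sec <- section_image(matrix(runif(400), 20, 20), mask, lm)
  expect_equal(dlgn_area(sec), 100)
  sec$pixel_area <- 2.5
  expect_equal(dlgn_area(sec), 250)
})

test_that("section triplets round-trip losslessly through TIFF/JSON", {
  ms <- phantom_fixture("contra")
  sec <- ms$series$sections[[2]]
  d <- withr::local_tempdir()
  write_section(sec, file.path(d, "img.tif"), file.path(d, "mask.tif"),
                file.path(d, "lm.json"), file.path(d, "mono.tif"))
  back <- read_section(file.path(d, "img.tif"), file.path(d, "mask.tif"),
                       file.path(d, "lm.json"))
  expect_equal(back$intensity, sec$intensity, ignore_attr = TRUE)
  expect_equal(back$dlgn_mask, sec$dlgn_mask, ignore_attr = TRUE)
  expect_equal(back$monocular_region, sec$monocular_region, ignore_attr = TRUE)
  expect_equal(back$landmarks$dm_tip, sec$landmarks$dm_tip)
  expect_equal(back$landmarks$outer_arc, sec$landmarks$outer_arc,
               ignore_attr = TRUE)
  expect_equal(back$pixel_area, sec$pixel_area)
})

test_that("series round-trip through a manifest directory preserves order", {
  ms <- phantom_fixture("ipsi")
  d <- withr::local_tempdir()
  write_series(ms$series, d)
  back <- read_series(d)
  expect_equal(length(back), length(ms$series))
  expect_equal(back$spacing_um, 50)
  expect_equal(vapply(back$sections, dlgn_area, numeric(1)),
               vapply(ms$series$sections, dlgn_area, numeric(1)))
})

test_that("malformed inputs yield distinct diagnostics", {
  d <- withr::local_tempdir()
  ms <- phantom_fixture("ipsi")
  sec <- ms$series$sections[[1]]
  write_section(sec, file.path(d, "img.tif"), file.path(d, "mask.tif"),
                file.path(d, "lm.json"))
  # mask of a different shape
  tiff::writeTIFF(matrix(1, 10, 10), file.path(d, "badmask.tif"),
                  bits.per.sample = 8)
  expect_error(read_section(file.path(d, "img.tif"), file.path(d, "badmask.tif"),
                            file.path(d, "lm.json")), "shape mismatch")
  # landmarks JSON missing dm_tip
  lm <- jsonlite::read_json(file.path(d, "lm.json"))
  lm$dm_tip <- NULL
  jsonlite::write_json(lm, file.path(d, "bad.json"), auto_unbox = TRUE)
  expect_error(read_section(file.path(d, "img.tif"), file.path(d, "mask.tif"),
                            file.path(d, "bad.json")), "dm_tip")
  expect_error(section_image(matrix(1, 3, 3), matrix(FALSE, 3, 3),
                             list(dm_tip = c(1, 1), vl_tip = c(3, 1),
                                  outer_arc = cbind(1:3, 1))), "empty")
})
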