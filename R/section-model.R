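#' Construct a coronal section image
#'
#' Bundles one coronal fluorescence section with everything the quantification
#' stages need: the intensity grid, the dLGN boundary mask, anatomical
#' landmarks and the off-nucleus background sampling region. Coordinates are
#' row-major with origin at the top-left pixel centre; dorsomedial is "up"
#' (lower row index). Pixels are unit squares of `pixel_area` square microns.
#'
#' @param intensity Numeric matrix of non-negative fluorescence values
#'   (arbitrary units).
#' @param dlgn_mask Logical matrix of the same shape delimiting the dLGN.
#' @param landmarks List with elements `dm_tip` and `vl_tip` (numeric
#'   `c(row, col)` on the mask boundary), `outer_arc` (n x 2 matrix of ordered
#'   boundary coordinates along the optic-tract-adjacent border), and
#'   optionally `background_region` (`c(r0, c0, h, w)`).
#' @param pixel_area Square microns per pixel (default 1.00).
#' @param monocular_region Optional logical matrix (subset of `dlgn_mask`)
#'   marking the ventrolateral monocular segment.
#' @return An object of class `section_image`.
#' @export
section_image <- function(intensity, dlgn_mask, landmarks,
                          pixel_area = 1.0, monocular_region = NULL) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("`intensity` must be a numeric matrix", call. = FALSE)
  if (any(intensity < 0)) stop("intensity values must be non-negative", call. = FALSE)
  dlgn_mask <- mask_as_logical(dlgn_mask)
  if (!identical(dim(intensity), dim(dlgn_mask)))
    stop("shape mismatch: intensity is ", paste(dim(intensity), collapse = "x"),
         " but dlgn_mask is ", paste(dim(dlgn_mask), collapse = "x"), call. = FALSE)
  if (!any(dlgn_mask)) stop("dlgn_mask is empty", call. = FALSE)
  for (key in c("dm_tip", "vl_tip", "outer_arc")) {
    if (is.null(landmarks[[key]]))
      stop("missing landmark: ", key, call. = FALSE)
  }
  if (!is.null(monocular_region)) {
    monocular_region <- mask_as_logical(monocular_region)
    if (!identical(dim(monocular_region), dim(dlgn_mask)))
      stop("shape mismatch: monocular_region", call. = FALSE)
    if (any(monocular_region & !dlgn_mask))
      stop("monocular_region must lie inside dlgn_mask", call. = FALSE)
  }
  landmarks$dm_tip <- as.numeric(landmarks$dm_tip)
  landmarks$vl_tip <- as.numeric(landmarks$vl_tip)
  landmarks$outer_arc <- as_coord_matrix(landmarks$outer_arc)
  structure(
    list(intensity = intensity, dlgn_mask = dlgn_mask, landmarks = landmarks,
         pixel_area = pixel_area, monocular_region = monocular_region),
    class = "section_image")
}

as_coord_matrix <- function(x) {
  if (is.list(x) && !is.matrix(x)) x <- do.call(rbind, lapply(x, as.numeric))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 2L) stop("coordinates must be n x 2 (row, col)", call. = FALSE)
  x
}

#' @export
print.section_image <- function(x, ...) {
  cat("<section_image> ", nrow(x$intensity), "x", ncol(x$intensity),
      " px, dLGN ", sum(x$dlgn_mask), " px (",
      format(dlgn_area(x), big.mark = ","), " um^2)\n", sep = "")
  invisible(x)
}

#' Construct an ordered serial section series
#'
#' Sections are stored rostral to caudal (rostral = lower index) at a fixed
#' inter-section spacing of 50 microns.
#'
#' @param sections List of [section_image()] objects, rostral first.
#' @param spacing_um Section spacing in microns (default 50).
#' @return An object of class `section_series`.
#' @export
section_series <- function(sections, spacing_um = 50) {
  stopifnot(is.list(sections), length(sections) >= 1L)
  ok <- vapply(sections, inherits, logical(1), "section_image")
  if (!all(ok)) stop("all elements must be section_image objects", call. = FALSE)
  pa <- vapply(sections, function(s) s$pixel_area, numeric(1))
  if (length(unique(pa)) != 1L)
    stop("all sections must share the same pixel_area", call. = FALSE)
  structure(list(sections = sections, spacing_um = spacing_um),
            class = "section_series")
}

#' @export
print.section_series <- function(x, ...) {
  cat("<section_series> ", length(x$sections), " sections, ",
      x$spacing_um, " um spacing\n", sep = "")
  invisible(x)
}

#' @export
length.section_series <- function(x) length(x$sections)

#' dLGN cross-sectional area of a section
#'
#' The area inside the delineated dLGN boundary: mask pixel count times the
#' pixel footprint.
#'
#' @param section A [section_image()].
#' @return Area in square microns.
#' @export
dlgn_area <- function(section) {
  stopifnot(inherits(section, "section_image"))
  if (!any(section$dlgn_mask)) stop("dlgn_mask is empty", call. = FALSE)
  sum(section$dlgn_mask) * section$pixel_area
}

#' Select the analysis section of a serial series
#'
#' The section used for quantification lies 100 microns rostral to the section
#' with the largest dLGN cross-sectional area, i.e. exactly two 50-micron
#' sections before the area argmax. Ties in area are broken toward the more
#' rostral (lower-index) section.
#'
#' @param series A [section_series()].
#' @return Integer index (1-based, rostral = 1) of the analysis section.
#' @export
select_analysis_section <- function(series) {
  stopifnot(inherits(series, "section_series"))
  if (length(series) < 3L)
    stop("need at least 3 sections to step 100 um rostral", call. = FALSE)
  areas <- vapply(series$sections, dlgn_area, numeric(1))
  amax <- which.max(areas)  # which.max returns the first (most rostral) tie
  idx <- amax - 2L
  if (idx < 1L)
    stop("insufficient rostral coverage: dLGN area peaks at section ", amax,
         "; no section 100 um rostral exists", call. = FALSE)
  idx
}

#' Place the default background sampling region
#'
#' The mean background is taken over a 40,000-pixel region ventromedial to the
#' dLGN. The default placement is a 200 x 200 axis-aligned square whose
#' top-right corner sits 10 px down-left (ventromedial in image coordinates,
#' dorsomedial being up) of the dLGN bounding box.
#'
#' @param section A [section_image()].
#' @return Integer vector `c(r0, c0, h, w)` (top-left corner, height, width).
#' @export
default_background_region <- function(section) {
  stopifnot(inherits(section, "section_image"))
  rows <- which(rowSums(section$dlgn_mask) > 0)
  cols <- which(colSums(section$dlgn_mask) > 0)
  r0 <- max(rows) + 10L
  c1 <- min(cols) - 10L
  c(r0 = r0, c0 = c1 - 199L, h = 200L, w = 200L)
}

#' Estimate the background fluorescence level
#'
#' Arithmetic mean intensity over a 40,000-pixel rectangle placed off the
#' nucleus (ventromedial to the dLGN). The region must fit inside the image
#' and be disjoint from the dLGN mask.
#'
#' @param section A [section_image()].
#' @param region Optional `c(r0, c0, h, w)`; defaults to the section's stored
#'   `background_region` landmark, falling back to
#'   [default_background_region()].
#' @return Scalar mean background intensity.
#' @export
estimate_background <- function(section, region = NULL) {
  stopifnot(inherits(section, "section_image"))
  if (is.null(region)) region <- section$landmarks$background_region
  if (is.null(region)) region <- default_background_region(section)
  region <- as.integer(round(region))
  r <- region[1]:(region[1] + region[3] - 1L)
  cc <- region[2]:(region[2] + region[4] - 1L)
  if (region[3] * region[4] != 40000L)
    stop("background region must contain exactly 40,000 pixels, got ",
         region[3] * region[4], call. = FALSE)
  if (min(r) < 1L || min(cc) < 1L || max(r) > nrow(section$intensity) ||
      max(cc) > ncol(section$intensity))
    stop("background region exceeds the image bounds", call. = FALSE)
  if (any(section$dlgn_mask[r, cc]))
    stop("background region overlaps the dLGN mask", call. = FALSE)
  mean(section$intensity[r, cc])
}

#' Subtract a scalar background level from a section
#'
#' Per-pixel `max(intensity - bg, 0)`; negative residuals are clamped to zero
#' because downstream thresholds compare against non-negative signal. Mask and
#' landmarks are unchanged.
#'
#' @param section A [section_image()].
#' @param bg Non-negative scalar background level.
#' @return A new [section_image()].
#' @export
subtract_background <- function(section, bg) {
  stopifnot(inherits(section, "section_image"), is.numeric(bg), length(bg) == 1L)
  if (bg < 0) stop("bg must be >= 0", call. = FALSE)
  section$intensity <- pmax(section$intensity - bg, 0)
  section
}
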