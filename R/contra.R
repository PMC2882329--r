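#' Reference mean Mc from the ventrolateral monocular segment
#'
#' Mean background-subtracted signal over 10,000 pixels of the ventrolateral
#' monocular segment of the dLGN — the region receiving only contralateral
#' input, hence fully labelled. The 10,000-pixel subsample is taken in raster
#' (column-major) order for reproducibility.
#'
#' @param section A background-subtracted [section_image()] with a
#'   `monocular_region`.
#' @param n_pixels Number of pixels averaged (default 10,000).
#' @return Scalar Mc.
#' @export
compute_Mc <- function(section, n_pixels = 10000L) {
  stopifnot(inherits(section, "section_image"))
  if (is.null(section$monocular_region))
    stop("section has no monocular_region annotation", call. = FALSE)
  idx <- which(section$monocular_region)
  if (length(idx) < n_pixels)
    stop("monocular segment has only ", length(idx), " px; need ", n_pixels,
         call. = FALSE)
  mean(section$intensity[idx[seq_len(n_pixels)]])
}

#' Contralateral threshold Tc from the monocular-segment mean
#'
#' `Tc = beta * Mc`, with a configurable coefficient defaulting to 0.5: half
#' the fully-labelled monocular level separates labelled territory from the
#' CTB-negative gap.
#'
#' @param Mc Positive reference mean.
#' @param beta Fraction in (0, 1).
#' @return Scalar Tc.
#' @export
threshold_Tc <- function(Mc, beta = 0.5) {
  if (!is.numeric(Mc) || length(Mc) != 1L || Mc <= 0)
    stop("Mc must be a positive scalar", call. = FALSE)
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)", call. = FALSE)
  beta * Mc
}

#' Measure the central gap of a contralateral section
#'
#' Pixels inside the dLGN with intensity strictly below Tc form two kinds of
#' regions: the central gap (the CTB-negative territory normally occupied by
#' the other eye's axons) and sub-threshold regions connected with the dLGN
#' contour. The contour-connected regions (4-connected components containing
#' a mask-boundary pixel) are excluded by flood fill; what remains is the gap.
#'
#' A section is flagged invalid — mirroring the discard rule for sections
#' whose gap reaches the contour — when a contour-connected sub-threshold
#' component penetrates deeper than `max_rim_depth` pixels into the nucleus
#' interior: central CTB-negative territory that drains to the contour cannot
#' be measured as a gap.
#'
#' @param section A background-subtracted [section_image()].
#' @param Tc Positive threshold.
#' @param max_rim_depth Tolerated penetration depth (px) of contour-connected
#'   sub-threshold regions before the section is declared invalid.
#' @return A one-row tibble `(gap_area_um2, gap_fraction_pct, valid)`; the
#'   area and fraction are `NA` when `valid` is `FALSE`.
#' @export
gap_size <- function(section, Tc, max_rim_depth = 5L) {
  stopifnot(inherits(section, "section_image"))
  if (!is.numeric(Tc) || length(Tc) != 1L || Tc <= 0)
    stop("Tc must be a positive scalar", call. = FALSE)
  sub <- section$dlgn_mask & section$intensity < Tc
  lab <- label_components(sub, connectivity = 4L)
  contour <- mask_contour(section$dlgn_mask)
  contour_labels <- unique(lab[contour & sub])
  contour_labels <- contour_labels[contour_labels > 0L]
  gap <- sub
  gap[lab %in% contour_labels] <- FALSE

  core <- erode_mask(section$dlgn_mask, max_rim_depth)
  deep_breach <- any((lab %in% contour_labels) & core)
  if (deep_breach)
    return(tibble::tibble(gap_area_um2 = NA_real_, gap_fraction_pct = NA_real_,
                          valid = FALSE))
  tibble::tibble(gap_area_um2 = sum(gap) * section$pixel_area,
                 gap_fraction_pct = 100 * sum(gap) / sum(section$dlgn_mask),
                 valid = TRUE)
}

#' Normalized dorsomedial-to-ventrolateral intensity profile
#'
#' Samples a straight strip 40 px wide running from the dorsomedial tip to
#' the ventrolateral tip of the dLGN, averages each 1 x 40 px transverse bin
#' (bilinear interpolation), and normalizes every bin mean by the mean of the
#' final 200 bins — the ventrolateral monocular segment of the strip (200 px
#' long by 40 px wide).
#'
#' @param section A background-subtracted [section_image()].
#' @param width Strip width in px (default 40).
#' @param norm_bins Number of trailing bins forming the monocular
#'   normalization segment (default 200).
#' @return An object of class `dlgn_profile`: a tibble
#'   `(distance_um, normalized_intensity)` with the raw bin means and the
#'   normalization divisor as attributes.
#' @export
intensity_profile <- function(section, width = 40L, norm_bins = 200L) {
  stopifnot(inherits(section, "section_image"))
  lm <- section$landmarks
  d <- lm$dm_tip; v <- lm$vl_tip
  len <- sqrt(sum((v - d)^2))
  n_bins <- floor(len) + 1L
  if (n_bins < norm_bins)
    stop("strip is ", n_bins, " bins long; need at least ", norm_bins,
         call. = FALSE)
  raw <- strip_bin_means(section$intensity, d, v, n_bins, width)
  divisor <- mean(raw[(n_bins - norm_bins + 1L):n_bins])
  if (!is.finite(divisor) || divisor <= 0)
    stop("normalization divisor must be positive", call. = FALSE)
  px_um <- sqrt(section$pixel_area)
  out <- tibble::tibble(distance_um = (seq_len(n_bins) - 1) * px_um,
                        normalized_intensity = raw / divisor)
  attr(out, "raw_means") <- raw
  attr(out, "divisor") <- divisor
  class(out) <- c("dlgn_profile", class(out))
  out
}

#' Normalized VGLUT1 profile with no-primary-antibody background
#'
#' Same strip construction as [intensity_profile()], but each bin mean has the
#' no-primary-antibody control mean subtracted (clamped at 0) and is then
#' divided by the whole-strip average, absorbing between-experiment intensity
#' differences.
#'
#' @param section A [section_image()]; the strip should traverse the central
#'   part of the CTB-positive ipsilateral projection.
#' @param no_primary_mean Mean fluorescence of the matched control section
#'   (>= 0).
#' @param width Strip width in px (default 40).
#' @return A `dlgn_profile` tibble `(distance_um, normalized_intensity)`.
#' @export
vglut1_profile <- function(section, no_primary_mean, width = 40L) {
  stopifnot(inherits(section, "section_image"))
  if (no_primary_mean < 0) stop("no_primary_mean must be >= 0", call. = FALSE)
  lm <- section$landmarks
  d <- lm$dm_tip; v <- lm$vl_tip
  len <- sqrt(sum((v - d)^2))
  n_bins <- floor(len) + 1L
  raw <- pmax(strip_bin_means(section$intensity, d, v, n_bins, width) -
                no_primary_mean, 0)
  divisor <- mean(raw)
  if (!is.finite(divisor) || divisor <= 0)
    stop("whole-strip average is zero; cannot normalize", call. = FALSE)
  px_um <- sqrt(section$pixel_area)
  out <- tibble::tibble(distance_um = (seq_len(n_bins) - 1) * px_um,
                        normalized_intensity = raw / divisor)
  attr(out, "raw_means") <- raw
  attr(out, "divisor") <- divisor
  class(out) <- c("dlgn_profile", class(out))
  out
}

# Mean intensity of each 1 x width transverse bin along the segment d -> v,
# sampled at 1-px steps with bilinear interpolation.
strip_bin_means <- function(intensity, d, v, n_bins, width) {
  u <- (v - d) / sqrt(sum((v - d)^2))
  nrm <- c(-u[2], u[1])
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, by = 1)
  t_along <- seq_len(n_bins) - 1
  rows <- outer(t_along * u[1], offs * nrm[1], `+`) + d[1]
  cols <- outer(t_along * u[2], offs * nrm[2], `+`) + d[2]
  vals <- bilinear_sample(intensity, rows, cols)
  rowMeans(matrix(vals, n_bins, length(offs)))
}

# Bilinear interpolation at (row, col) positions; positions outside the image
# are clamped to the border pixel.
bilinear_sample <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(as.vector(rows), 1), nr)
  cc <- pmin(pmax(as.vector(cols), 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  fr <- r - r0; fc <- cc - c0
  i00 <- (c0 - 1) * nr + r0
  m[i00] * (1 - fr) * (1 - fc) + m[i00 + 1] * fr * (1 - fc) +
    m[i00 + nr] * (1 - fr) * fc + m[i00 + nr + 1] * fr * fc
}
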