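#' Read a section from its image/mask/landmarks triplet
#'
#' Reads a grayscale TIFF intensity image (8- or 16-bit), a binary TIFF dLGN
#' mask of the same shape, and a landmarks JSON file with schema
#' `{dm_tip: [r, c], vl_tip: [r, c], outer_arc: [[r, c], ...],
#'   monocular_region: <mask path>, background_region: [r0, c0, h, w],
#'   pixel_area: <um^2>}`.
#' Coordinates are 1-based `(row, col)` pixel positions. A relative
#' `monocular_region` path is resolved against the landmarks file directory.
#'
#' @param image_path,mask_path,landmarks_path File paths.
#' @return A [section_image()].
#' @export
read_section <- function(image_path, mask_path, landmarks_path) {
  img <- read_gray_tiff(image_path)
  msk <- read_gray_tiff(mask_path) > 0
  if (!identical(dim(img), dim(msk)))
    stop("shape mismatch: image is ", paste(dim(img), collapse = "x"),
         " but mask is ", paste(dim(msk), collapse = "x"), call. = FALSE)
  lm <- jsonlite::read_json(landmarks_path, simplifyVector = TRUE)
  for (key in c("dm_tip", "vl_tip", "outer_arc")) {
    if (is.null(lm[[key]])) stop("missing landmark: ", key, call. = FALSE)
  }
  mono <- NULL
  if (!is.null(lm$monocular_region) && is.character(lm$monocular_region)) {
    mono_path <- lm$monocular_region
    if (!file.exists(mono_path))
      mono_path <- file.path(dirname(landmarks_path), mono_path)
    mono <- read_gray_tiff(mono_path) > 0
    lm$monocular_region <- NULL
  }
  pixel_area <- if (is.null(lm$pixel_area)) 1.0 else as.numeric(lm$pixel_area)
  lm$pixel_area <- NULL
  section_image(img, msk, lm, pixel_area = pixel_area, monocular_region = mono)
}

#' Write a section as a TIFF/TIFF/JSON triplet
#'
#' Intensities are stored as 16-bit grayscale TIFF (values are rounded and
#' clipped to 0..65535), masks as 8-bit binary TIFF, landmarks as JSON. The
#' round trip through [read_section()] is lossless for integer-valued
#' intensities.
#'
#' @param section A [section_image()].
#' @param image_path,mask_path,landmarks_path Output paths.
#' @param monocular_path Optional path for the monocular-segment mask; required
#'   when the section carries one.
#' @return Invisibly, the landmarks path.
#' @export
write_section <- function(section, image_path, mask_path, landmarks_path,
                          monocular_path = NULL) {
  stopifnot(inherits(section, "section_image"))
  write_gray_tiff(section$intensity, image_path, bits = 16L)
  write_gray_tiff(section$dlgn_mask * 65535, mask_path, bits = 8L)
  lm <- section$landmarks
  out <- list(
    dm_tip = lm$dm_tip, vl_tip = lm$vl_tip,
    outer_arc = unname(lm$outer_arc),
    pixel_area = section$pixel_area)
  if (!is.null(lm$background_region))
    out$background_region <- unname(lm$background_region)
  if (!is.null(section$monocular_region)) {
    if (is.null(monocular_path))
      stop("section has a monocular_region; supply monocular_path", call. = FALSE)
    write_gray_tiff(section$monocular_region * 65535, monocular_path, bits = 8L)
    out$monocular_region <- basename(monocular_path)
  }
  jsonlite::write_json(out, landmarks_path, auto_unbox = TRUE, digits = NA)
  invisible(landmarks_path)
}

read_gray_tiff <- function(path) {
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  storage.mode(x) <- "double"
  x
}

write_gray_tiff <- function(m, path, bits = 16L) {
  top <- 2^bits - 1
  m <- pmin(pmax(round(m), 0), top) / top
  tiff::writeTIFF(m, path, bits.per.sample = bits)
}

#' Write a section series to a directory with a YAML manifest
#'
#' Each section becomes `section_<i>_{image,mask,landmarks,monocular}` files;
#' `manifest.yaml` records the rostral-to-caudal order (rostral first, lower
#' index), the 50-micron spacing and per-section file names.
#'
#' @param series A [section_series()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "section_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", length(series))
  for (i in seq_along(series$sections)) {
    s <- series$sections[[i]]
    base <- sprintf("section_%02d", i)
    mono <- if (!is.null(s$monocular_region)) paste0(base, "_monocular.tif")
    write_section(
      s,
      file.path(dir, paste0(base, "_image.tif")),
      file.path(dir, paste0(base, "_mask.tif")),
      file.path(dir, paste0(base, "_landmarks.json")),
      if (!is.null(mono)) file.path(dir, mono))
    entries[[i]] <- list(image = paste0(base, "_image.tif"),
                         mask = paste0(base, "_mask.tif"),
                         landmarks = paste0(base, "_landmarks.json"))
  }
  manifest <- list(orientation = "rostral_first",
                   spacing_um = series$spacing_um,
                   sections = entries)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a section series from a manifest directory
#'
#' @param dir Directory containing `manifest.yaml` as written by
#'   [write_series()].
#' @return A [section_series()].
#' @export
read_series <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  sections <- lapply(manifest$sections, function(e)
    read_section(file.path(dir, e$image), file.path(dir, e$mask),
                 file.path(dir, e$landmarks)))
  section_series(sections, spacing_um = manifest$spacing_um)
}
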