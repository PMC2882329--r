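#' Centre of mass of the ipsilateral patches
#'
#' Unweighted centroid of the union of all retained patch pixels; the patch
#' set is binary, so intensities play no role.
#'
#' @param patches A [extract_patches()] result.
#' @return Numeric `c(row, col)`.
#' @export
patch_centroid <- function(patches) {
  stopifnot(inherits(patches, "patch_set"))
  if (patch_set_empty(patches))
    stop("patch set is empty; centroid undefined", call. = FALSE)
  px <- do.call(rbind, patches$pixels)
  c(mean(px[, 1]), mean(px[, 2]))
}

#' Patch extent along the dorsomedial-ventrolateral axis
#'
#' Line r joins the dorsomedial tip D to the ventrolateral tip V. Lines
#' parallel to r are swept across the dLGN at 1-px offsets; on each, the patch
#' span is the distance between the outermost patch intersections (two
#' endpoints, not summed runs). The line r' maximizing that span gives
#' `Q1Q2` (the patch length) and `DprimeVprime` (the dLGN chord on r');
#' ties are broken toward the larger chord, then the smaller absolute offset.
#'
#' @param section A [section_image()] with `dm_tip`/`vl_tip` landmarks.
#' @param patches A non-empty [extract_patches()] result.
#' @return One-row tibble `(Q1Q2_um, DpVp_um, norm_dmvl_pct, offset_px)`.
#' @export
dmvl_length <- function(section, patches) {
  stopifnot(inherits(section, "section_image"), inherits(patches, "patch_set"))
  if (patch_set_empty(patches))
    stop("patch set is empty; DM-VL length undefined", call. = FALSE)
  res <- sweep_dmvl(section$dlgn_mask, patches$mask,
                    section$landmarks$dm_tip, section$landmarks$vl_tip)
  px_um <- sqrt(section$pixel_area)
  tibble::tibble(Q1Q2_um = res$Q1Q2 * px_um, DpVp_um = res$DpVp * px_um,
                 norm_dmvl_pct = res$norm, offset_px = res$offset)
}

#' Patch extent along the outer-inner axis
#'
#' Line s passes through the patch centre of mass C perpendicular to the dLGN
#' surface: the local surface tangent is fitted by total least squares over an
#' 11-point window of the outer boundary arc centred on the arc point nearest
#' C. `LM` is the dLGN chord on s from the first outer-boundary crossing to
#' the last opposite-boundary crossing; `P1P2` is the span between the
#' outermost patch intersections on s (0 when s misses the patch).
#'
#' @param section A [section_image()] with an `outer_arc` landmark.
#' @param patches A non-empty [extract_patches()] result.
#' @param tangent_window Number of arc points in the tangent fit (default 11).
#' @return One-row tibble `(P1P2_um, LM_um, norm_oi_pct)`.
#' @export
oi_length <- function(section, patches, tangent_window = 11L) {
  stopifnot(inherits(section, "section_image"), inherits(patches, "patch_set"))
  if (patch_set_empty(patches))
    stop("patch set is empty; O-I length undefined", call. = FALSE)
  res <- oi_from_masks(section$dlgn_mask, patches$mask, patch_centroid(patches),
                       section$landmarks$outer_arc, tangent_window)
  px_um <- sqrt(section$pixel_area)
  tibble::tibble(P1P2_um = res$P1P2 * px_um, LM_um = res$LM * px_um,
                 norm_oi_pct = res$norm)
}

#' Both axis measurements of a section
#'
#' @inheritParams oi_length
#' @return One-row tibble with the [dmvl_length()] and [oi_length()] columns.
#' @export
measure_axis_lengths <- function(section, patches, tangent_window = 11L) {
  dplyr::bind_cols(dmvl_length(section, patches)[, 1:3],
                   oi_length(section, patches, tangent_window))
}

# --- internal geometry on raw masks (also used for phantom ground truth) ----

measure_axes_masks <- function(dlgn_mask, patch_mask, dm_tip, vl_tip,
                               outer_arc, tangent_window = 11L) {
  dm <- sweep_dmvl(dlgn_mask, patch_mask, dm_tip, vl_tip)
  ctr <- {
    px <- which(patch_mask, arr.ind = TRUE)
    c(mean(px[, 1]), mean(px[, 2]))
  }
  oi <- oi_from_masks(dlgn_mask, patch_mask, ctr, outer_arc, tangent_window)
  list(Q1Q2 = dm$Q1Q2, DpVp = dm$DpVp, norm_dmvl = dm$norm,
       P1P2 = oi$P1P2, LM = oi$LM, norm_oi = oi$norm)
}

# Sweep lines parallel to D->V at 1-px offsets. Spans follow the unit-square
# pixel convention: span = max projection - min projection + 1.
sweep_dmvl <- function(dlgn_mask, patch_mask, dm_tip, vl_tip) {
  u <- vl_tip - dm_tip
  u <- u / sqrt(sum(u^2))
  nv <- c(-u[2], u[1])
  proj <- function(mask) {
    px <- which(mask, arr.ind = TRUE)
    dr <- px[, 1] - dm_tip[1]; dc <- px[, 2] - dm_tip[2]
    list(off = round(dr * nv[1] + dc * nv[2]),
         t = dr * u[1] + dc * u[2])
  }
  dp <- proj(dlgn_mask)
  pp <- proj(patch_mask)
  p_span <- tapply(pp$t, pp$off, function(t) max(t) - min(t) + 1)
  d_span <- tapply(dp$t, dp$off, function(t) max(t) - min(t) + 1)
  offs <- as.numeric(names(p_span))
  chord <- d_span[names(p_span)]
  chord[is.na(chord)] <- 0
  best <- order(-p_span, -chord, abs(offs))[1]
  q <- unname(p_span[best])
  dpv <- unname(chord[best])
  list(Q1Q2 = q, DpVp = dpv,
       norm = if (dpv > 0) 100 * min(q / dpv, 1) else NA_real_,
       offset = offs[best])
}

oi_from_masks <- function(dlgn_mask, patch_mask, centre, outer_arc,
                          tangent_window = 11L) {
  arc <- as_coord_matrix(outer_arc)
  d2 <- (arc[, 1] - centre[1])^2 + (arc[, 2] - centre[2])^2
  i0 <- which.min(d2)
  hw <- (tangent_window - 1L) %/% 2L
  lo <- max(1L, i0 - hw); hi <- min(nrow(arc), i0 + hw)
  win <- arc[lo:hi, , drop = FALSE]
  if (nrow(win) < 2L) stop("outer arc too short for a tangent fit", call. = FALSE)
  cw <- sweep(win, 2, colMeans(win))
  sv <- svd(cw)
  tangent <- sv$v[, 1]
  if (sv$d[2] / max(sv$d[1], 1e-12) > 0.9)
    stop("degenerate tangent: arc window has no dominant direction",
         call. = FALSE)
  radial <- centre - arc[i0, ]
  rl <- sqrt(sum(radial^2))
  if (rl > 1e-9) {
    cosang <- abs(sum(tangent * radial)) / rl
    if (cosang > 0.99)
      stop("degenerate tangent: window collinear with the radius", call. = FALSE)
  }
  nrm <- c(-tangent[2], tangent[1])
  if (rl > 1e-9 && sum(nrm * radial) < 0) nrm <- -nrm  # point inward

  step <- 0.25
  diag_len <- sqrt(nrow(dlgn_mask)^2 + ncol(dlgn_mask)^2)
  tt <- seq(-diag_len, diag_len, by = step)
  rows <- round(centre[1] + tt * nrm[1])
  cols <- round(centre[2] + tt * nrm[2])
  ok <- rows >= 1 & rows <= nrow(dlgn_mask) & cols >= 1 & cols <= ncol(dlgn_mask)
  lin <- (cols[ok] - 1L) * nrow(dlgn_mask) + rows[ok]
  tt <- tt[ok]
  inside <- dlgn_mask[lin]
  if (!any(inside)) stop("line s does not intersect the dLGN", call. = FALSE)
  lm_span <- (max(tt[inside]) + step / 2) - (min(tt[inside]) - step / 2)
  in_patch <- patch_mask[lin]
  p_span <- if (any(in_patch))
    (max(tt[in_patch]) + step / 2) - (min(tt[in_patch]) - step / 2) else 0
  list(P1P2 = p_span, LM = lm_span, norm = 100 * min(p_span / lm_span, 1))
}
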