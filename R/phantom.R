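#' Specify a synthetic dLGN section phantom
#'
#' Defines a parametric crescent-shaped dLGN (two concentric circular arcs
#' sharing a centre) rendered into a serial coronal section stack with known
#' ground truth. A phantom emulates either an ipsilateral section (a single
#' supra-background patch of tracer label inside an otherwise unlabelled
#' nucleus) when `patch_fraction > 0`, or a contralateral section (near-full
#' labelling with a central label-free gap) when `gap_fraction > 0`. The two
#' signals come from different hemispheres in a real animal, so a single
#' rendered section accepts at most one of the two.
#'
#' The crescent is centred on `centroid` (row, col), spans
#' `angular_span` radians symmetric about the image x-axis, with dorsomedial
#' "up": the dorsomedial tip D sits at the top end of the outer arc, the
#' ventrolateral tip V at the bottom end. Across the stack the radii scale as
#' `1 - shrink * |i - mid|` so the cross-sectional area has a unique maximum
#' at the middle section, as a real nucleus does.
#'
#' Axis-extent control: the ipsilateral patch is an angular sector clipped to
#' a radial band. The band thickness (fraction `oi` of the outer-to-inner
#' nucleus thickness) fixes the true outer-inner extent exactly; the sector
#' half-width is solved numerically so the true dorsomedial-ventrolateral
#' extent of the rendered patch matches the `dmvl` target. When
#' `patch_axis_extents` is `NULL` the sector width is instead derived in
#' closed form from `patch_fraction`.
#'
#' @param patch_fraction Target ipsilateral patch area / dLGN area, in
#'   `[0, 1)`.
#' @param gap_fraction Target gap area / dLGN area, in `[0, 1)`.
#' @param patch_axis_extents Optional `c(dmvl = , oi = )` target normalized
#'   extents in percent of axis length; overrides `patch_fraction`.
#' @param label_intensity Mean foreground signal (ADU, 16-bit scale).
#' @param background_level Mean off-signal intensity (ADU).
#' @param noise_sd Additive Gaussian noise SD (ADU).
#' @param bias_amplitude Amplitude of the smooth multiplicative illumination
#'   bias (0 disables it).
#' @param n_sections Odd section count, at least 5.
#' @param seed Integer RNG seed.
#' @param outer_radius,inner_radius Arc radii of the full-size (middle)
#'   section, pixels (= microns at the 1.00 um^2/px scale).
#' @param angular_span Total angular span of the crescent, radians.
#' @param centroid Arc centre `c(row, col)`.
#' @param image_shape Image `c(rows, cols)`.
#' @param patch_theta Angular centre of the patch sector, radians (0 = mid
#'   crescent, positive = dorsomedial).
#' @param patch_oi_extent Radial thickness of the patch as a fraction of
#'   nucleus thickness, used when `patch_axis_extents` is `NULL`.
#' @param gap_theta Angular position of the gap centre, radians.
#' @param gap_touches_contour If `TRUE` the gap is deliberately opened to the
#'   nucleus contour (renders a section the gap analysis must discard).
#' @param rim_px Width in px of the unlabelled rim inside the contour of
#'   contralateral sections (exercises the flood-fill exclusion).
#' @param monocular_span_frac Fraction of the angular span, taken from the
#'   ventrolateral end, forming the monocular segment.
#' @param shrink Per-section radial shrink rate away from the middle section.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(patch_fraction = 0,
                         gap_fraction = 0,
                         patch_axis_extents = NULL,
                         label_intensity = 3000,
                         background_level = 500,
                         noise_sd = 0,
                         bias_amplitude = 0,
                         n_sections = 7L,
                         seed = 1L,
                         outer_radius = 220,
                         inner_radius = 80,
                         angular_span = 2 * pi / 3,
                         centroid = c(300, 250),
                         image_shape = c(700, 540),
                         patch_theta = 20 * pi / 180,
                         patch_oi_extent = 0.8,
                         gap_theta = 10 * pi / 180,
                         gap_touches_contour = FALSE,
                         rim_px = 2L,
                         monocular_span_frac = 0.35,
                         shrink = 0.08) {
  if (noise_sd < 0) stop("invalid spec: noise_sd must be >= 0", call. = FALSE)
  if (label_intensity < 0 || background_level < 0)
    stop("invalid spec: intensities must be >= 0", call. = FALSE)
  if (patch_fraction < 0 || patch_fraction >= 1 ||
      gap_fraction < 0 || gap_fraction >= 1)
    stop("invalid spec: fractions must lie in [0, 1)", call. = FALSE)
  if (patch_fraction > 0 && gap_fraction > 0)
    stop("invalid spec: a section carries either an ipsilateral patch or a ",
         "contralateral gap, not both (they are different hemispheres)",
         call. = FALSE)
  n_sections <- as.integer(n_sections)
  if (n_sections < 5L || n_sections %% 2L == 0L)
    stop("invalid spec: n_sections must be odd and >= 5", call. = FALSE)
  if (inner_radius <= 0 || outer_radius <= inner_radius)
    stop("invalid spec: need 0 < inner_radius < outer_radius", call. = FALSE)
  if (!is.null(patch_axis_extents)) {
    if (is.null(names(patch_axis_extents)))
      names(patch_axis_extents) <- c("dmvl", "oi")
    stopifnot(all(c("dmvl", "oi") %in% names(patch_axis_extents)))
  }
  spec <- structure(as.list(environment()), class = "phantom_spec")
  spec$.cache <- new.env(parent = emptyenv())
  # Geometric feasibility of the gap: the hole must sit strictly interior
  # even in the smallest (end) sections
  if (gap_fraction > 0 && !gap_touches_contour) {
    g <- gap_geometry(spec, section_scale(spec, 1L))
    if (!g$interior)
      stop("invalid spec: gap of fraction ", gap_fraction,
           " cannot sit strictly interior to the nucleus", call. = FALSE)
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  mode <- if (x$gap_fraction > 0) "contralateral (gap)" else
    if (x$patch_fraction > 0 || !is.null(x$patch_axis_extents))
      "ipsilateral (patch)" else "blank"
  cat("<phantom_spec> ", mode, ", ", x$n_sections, " sections, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

# Radial scale factor of section i (1-based); unique max at the middle section
section_scale <- function(spec, i) {
  mid <- (spec$n_sections + 1L) / 2
  1 - spec$shrink * abs(i - mid)
}

analysis_index <- function(spec) (spec$n_sections + 1L) %/% 2L - 2L

# Polar coordinate fields of the phantom image plane
phantom_polar <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  y <- spec$centroid[1] - matrix(seq_len(nr), nr, nc)        # up-positive
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - spec$centroid[2]
  list(r = sqrt(x^2 + y^2), theta = atan2(y, x))
}

crescent_mask <- function(spec, k, polar = phantom_polar(spec)) {
  half <- spec$angular_span / 2
  polar$r >= spec$inner_radius * k & polar$r <= spec$outer_radius * k &
    abs(polar$theta) <= half
}

# Patch sector geometry at unit scale; delta solved from area or dmvl target
patch_geometry <- function(spec) {
  thick <- spec$outer_radius - spec$inner_radius
  rmid <- (spec$outer_radius + spec$inner_radius) / 2
  f_oi <- if (!is.null(spec$patch_axis_extents))
    spec$patch_axis_extents[["oi"]] / 100 else spec$patch_oi_extent
  a <- rmid - f_oi * thick / 2
  b <- rmid + f_oi * thick / 2
  area_dlgn <- 0.5 * spec$angular_span * (spec$outer_radius^2 - spec$inner_radius^2)
  if (is.null(spec$patch_axis_extents)) {
    delta <- spec$patch_fraction * area_dlgn / (b^2 - a^2)
  } else if (!is.null(spec$.cache$delta)) {
    delta <- spec$.cache$delta
  } else {
    delta <- solve_patch_delta(spec, a, b)
    if (!is.null(spec$.cache)) spec$.cache$delta <- delta
  }
  half <- spec$angular_span / 2
  if (spec$patch_theta + delta > half || spec$patch_theta - delta < -half)
    stop("invalid spec: patch sector does not fit inside the nucleus span",
         call. = FALSE)
  list(a = a, b = b, delta = delta, f_oi = f_oi)
}

patch_mask_at <- function(spec, k, geom, polar = phantom_polar(spec)) {
  if (geom$delta <= 0) return(matrix(FALSE, spec$image_shape[1], spec$image_shape[2]))
  polar$r >= geom$a * k & polar$r <= geom$b * k &
    polar$theta >= spec$patch_theta - geom$delta &
    polar$theta <= spec$patch_theta + geom$delta &
    crescent_mask(spec, k, polar)
}

# Bisection on the sector half-width so that the rendered patch's true
# normalized DM-VL extent (measured on the analysis-section masks) matches
# the requested target.
solve_patch_delta <- function(spec, a, b) {
  target <- spec$patch_axis_extents[["dmvl"]]
  k <- section_scale(spec, analysis_index(spec))
  polar <- phantom_polar(spec)
  dlgn <- crescent_mask(spec, k, polar)
  lms <- phantom_landmarks(spec, k)
  half <- spec$angular_span / 2
  hi <- min(half - spec$patch_theta, half + spec$patch_theta) - 1e-3
  measure <- function(delta) {
    g <- list(a = a, b = b, delta = delta)
    pm <- patch_mask_at(spec, k, g, polar)
    if (!any(pm)) return(0)
    ax <- measure_axes_masks(dlgn, pm, lms$dm_tip, lms$vl_tip, lms$outer_arc)
    ax$norm_dmvl
  }
  lo <- 0.005
  if (measure(hi) < target)
    stop("invalid spec: requested DM-VL extent unattainable", call. = FALSE)
  for (i in 1:18) {
    mid <- (lo + hi) / 2
    if (measure(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

gap_geometry <- function(spec, k) {
  area <- 0.5 * spec$angular_span *
    (spec$outer_radius^2 - spec$inner_radius^2) * k^2
  rg <- sqrt(spec$gap_fraction * area / pi)
  rmid <- (spec$outer_radius + spec$inner_radius) / 2 * k
  centre_r <- if (spec$gap_touches_contour) spec$inner_radius * k else rmid
  margin <- spec$rim_px + 2
  interior <- (centre_r - rg > spec$inner_radius * k + margin) &&
    (centre_r + rg < spec$outer_radius * k - margin) &&
    (abs(spec$gap_theta) + asin(min(1, rg / centre_r)) <
       spec$angular_span / 2 - 0.02)
  list(rg = rg, centre_r = centre_r, interior = interior && !spec$gap_touches_contour)
}

phantom_landmarks <- function(spec, k) {
  half <- spec$angular_span / 2
  cy <- spec$centroid[1]; cx <- spec$centroid[2]
  Ro <- spec$outer_radius * k
  pt <- function(theta, r) c(cy - r * sin(theta), cx + r * cos(theta))
  thetas <- seq(half, -half, by = -0.5 * pi / 180)
  arc <- t(vapply(thetas, function(th) pt(th, Ro), numeric(2)))
  list(dm_tip = pt(half, Ro), vl_tip = pt(-half, Ro), outer_arc = arc)
}

#' Render one synthetic section with its ground truth
#'
#' Deterministic given `(spec, section_index)`: the same call yields
#' bit-identical images. Intensities are quantized to integer ADU, as a camera
#' would, so written TIFFs round-trip losslessly.
#'
#' @param spec A [phantom_spec()].
#' @param section_index 1-based index in `1..n_sections` (rostral = 1).
#' @return A list with elements `section` (a [section_image()]) and `truth`
#'   (per-section ground-truth record: exact pixel counts, fractions in
#'   percent, and — for patch sections — true axis lengths measured on the
#'   noise-free masks).
#' @export
render_section <- function(spec, section_index) {
  stopifnot(inherits(spec, "phantom_spec"))
  section_index <- as.integer(section_index)
  if (section_index < 1L || section_index > spec$n_sections)
    stop("section_index out of range", call. = FALSE)
  k <- section_scale(spec, section_index)
  polar <- phantom_polar(spec)
  dlgn <- crescent_mask(spec, k, polar)
  lms <- phantom_landmarks(spec, k)

  base <- matrix(spec$background_level, spec$image_shape[1], spec$image_shape[2])
  truth <- list(section_index = section_index, scale = k,
                dlgn_px = sum(dlgn),
                patch_px = 0L, patch_fraction_pct = 0,
                gap_px = 0L, gap_fraction_pct = 0, gap_valid = NA)
  patch_mask <- NULL

  mode_ipsi <- spec$patch_fraction > 0 || !is.null(spec$patch_axis_extents)
  if (mode_ipsi) {
    geom <- patch_geometry(spec)
    patch_mask <- patch_mask_at(spec, k, geom, polar)
    base[patch_mask] <- spec$label_intensity
    truth$patch_px <- sum(patch_mask)
    truth$patch_fraction_pct <- 100 * truth$patch_px / truth$dlgn_px
    if (any(patch_mask)) {
      ax <- measure_axes_masks(dlgn, patch_mask, lms$dm_tip, lms$vl_tip,
                               lms$outer_arc)
      truth[c("Q1Q2", "DpVp", "norm_dmvl", "P1P2", "LM", "norm_oi")] <-
        ax[c("Q1Q2", "DpVp", "norm_dmvl", "P1P2", "LM", "norm_oi")]
    }
  } else if (spec$gap_fraction > 0) {
    core <- dlgn & !erosion_rim(dlgn, spec$rim_px)
    gg <- gap_geometry(spec, k)
    gcy <- spec$centroid[1] - gg$centre_r * sin(spec$gap_theta)
    gcx <- spec$centroid[2] + gg$centre_r * cos(spec$gap_theta)
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    dy <- matrix(seq_len(nr), nr, nc) - gcy
    dx <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - gcx
    hole <- (dx^2 + dy^2) <= gg$rg^2
    base[core & !hole] <- spec$label_intensity
    gap_mask <- core & hole
    truth$gap_px <- sum(gap_mask)
    truth$gap_fraction_pct <- 100 * truth$gap_px / truth$dlgn_px
    truth$gap_valid <- gg$interior
  }

  if (spec$bias_amplitude > 0) {
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    u <- (matrix(seq_len(nr), nr, nc) / nr - 0.5) * 2
    v <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) / nc - 0.5) * 2
    base <- base * (1 + spec$bias_amplitude * (u + v) / 2)
  }
  if (spec$noise_sd > 0) {
    base <- base + with_phantom_seed(spec$seed, section_index, {
      matrix(stats::rnorm(length(base), sd = spec$noise_sd),
             nrow(base), ncol(base))
    })
  }
  intensity <- pmin(pmax(round(base), 0), 65535)

  # The monocular-segment annotation is only meaningful for contralateral
  # sections, where the segment is fully labelled and anchors Mc
  mono <- NULL
  if (spec$gap_fraction > 0) {
    half <- spec$angular_span / 2
    mono <- dlgn &
      polar$theta <= (-half + spec$monocular_span_frac * spec$angular_span) &
      polar$theta >= -half
    truth$mono_px <- sum(mono)
  }
  sec <- section_image(intensity, dlgn, lms, pixel_area = 1.0,
                       monocular_region = mono)
  sec$landmarks$background_region <- default_background_region(sec)
  list(section = sec, truth = truth)
}

# rim of width n just inside the mask contour
erosion_rim <- function(mask, n) mask & !erode_mask(mask, n)

with_phantom_seed <- function(seed, section_index, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) * 131L + section_index * 7919L) %% 2147483629L)
  force(expr)
}

#' Render a full serial phantom series
#'
#' @param spec A [phantom_spec()].
#' @return A list with `series` (a [section_series()], rostral first, 50-um
#'   spacing, dLGN area peaking at the middle section) and `truth` (spec echo
#'   plus the per-section truth records and the analysis-section index).
#' @export
make_series <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$n_sections < 5L) stop("need n_sections >= 5", call. = FALSE)
  rendered <- lapply(seq_len(spec$n_sections), function(i) render_section(spec, i))
  series <- section_series(lapply(rendered, `[[`, "section"), spacing_um = 50)
  truth <- list(spec = spec,
                sections = lapply(rendered, `[[`, "truth"),
                analysis_index = analysis_index(spec))
  list(series = series, truth = truth)
}

#' Specify one cohort group by its printed summary
#'
#' @param label Group label.
#' @param mean,sd Group mean and standard deviation (percent units).
#' @param n Number of animals (>= 2).
#' @return A one-row tibble.
#' @export
cohort_spec <- function(label, mean, sd, n) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  tibble::tibble(group = label, mean = mean, sd = sd, n = as.integer(n))
}

#' Draw per-animal endpoint values for a set of cohort groups
#'
#' Samples each group's per-animal measured endpoint (e.g. the percent area
#' fraction) from Normal(mean, sd) truncated at 0 — percentages cannot be
#' negative. This endpoint-level mode feeds the statistics stage directly;
#' image-parameter draws for pipeline-recovery runs are a separate mode (see
#' [run_quantification()]).
#'
#' @param groups A data frame with columns `group`, `mean`, `sd`, `n` (rows
#'   from [cohort_spec()] or a preset from [cohort_preset()]).
#' @param seed Integer RNG seed.
#' @return A tibble `(group, animal, value)` carrying the generating triplets
#'   as attribute `"truth"`.
#' @export
simulate_cohort <- function(groups, seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("group", "mean", "sd", "n") %in% names(groups)))
  if (any(groups$n < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (any(groups$sd < 0)) stop("sd must be >= 0", call. = FALSE)
  draws <- with_phantom_seed(seed, 0L, {
    purrr::pmap(groups, function(group, mean, sd, n, ...) {
      vals <- if (sd == 0) rep(mean, n) else {
        v <- stats::rnorm(n, mean, sd)
        while (any(v < 0)) v[v < 0] <- stats::rnorm(sum(v < 0), mean, sd)
        v
      }
      tibble::tibble(group = group, animal = seq_len(n), value = vals)
    })
  })
  out <- dplyr::bind_rows(draws)
  attr(out, "truth") <- tibble::as_tibble(groups)
  out
}

#' Printed cohort summaries of the study, as presets
#'
#' Each preset encodes one figure's two-group comparison exactly as printed
#' (group mean, SD, n in percent or square microns), together with the test
#' the authors report for it.
#'
#' @param name Preset name; call with no arguments to list all presets.
#' @return A tibble `(group, mean, sd, n)` with attributes `named_test`
#'   (`"student"` or `"welch"`), `p_bound` (the printed significance bound,
#'   or the printed exact p for null results) and `units`.
#' @export
cohort_preset <- function(name = NULL) {
  p <- list(
    Fig2A = list(g = rbind(c("ME", 22.1, 3.6, 5), c("control", 10.8, 1.2, 3)),
                 test = "student", p_bound = 0.01, units = "percent"),
    Fig2B = list(g = rbind(c("ME", 3.16, 1.11, 4), c("control", 16.46, 6.24, 4)),
                 test = "welch", p_bound = 0.05, units = "percent"),
    Fig4_P22 = list(g = rbind(c("ME", 15.5, 1.2, 4), c("control", 12.5, 1.7, 4)),
                    test = "student", p_bound = 0.05, units = "percent"),
    Fig4_P34 = list(g = rbind(c("ME", 13.6, 0.5, 4), c("control", 13.3, 3.7, 4)),
                    test = "welch", p_bound = NA, p_exact = 0.91, units = "percent"),
    Fig6A_MD = list(g = rbind(c("MD", 9.8, 1.5, 4), c("control", 10.8, 1.2, 3)),
                    test = "student", p_bound = NA, p_exact = 0.46, units = "percent"),
    Fig6B_TTX = list(g = rbind(c("TTX", 15.2, 3.3, 18), c("saline", 11.7, 1.1, 8)),
                     test = "welch", p_bound = 0.01, units = "percent"),
    Fig6B_TTX_vs_ME = list(g = rbind(c("TTX", 15.2, 3.3, 18), c("ME", 20.7, 2.3, 3)),
                           test = "student", p_bound = 0.05, units = "percent"),
    S1_ctb_area = list(g = rbind(c("ME", 43673, 5990, 5), c("control", 27858, 3294, 3)),
                       test = "student", p_bound = 0.05, units = "um2"),
    S1_dlgn_area = list(g = rbind(c("ME", 198680, 15054, 5), c("control", 257559, 6849, 3)),
                        test = "student", p_bound = 0.01, units = "um2"))
  if (is.null(name)) return(names(p))
  if (!name %in% names(p))
    stop("unknown preset '", name, "'; see cohort_preset() for the list",
         call. = FALSE)
  x <- p[[name]]
  out <- tibble::tibble(group = x$g[, 1],
                        mean = as.numeric(x$g[, 2]),
                        sd = as.numeric(x$g[, 3]),
                        n = as.integer(x$g[, 4]))
  attr(out, "named_test") <- x$test
  attr(out, "p_bound") <- x$p_bound
  if (!is.null(x$p_exact)) attr(out, "p_exact") <- x$p_exact
  attr(out, "units") <- x$units
  out
}
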