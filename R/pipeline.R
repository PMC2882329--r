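#' Quantify one animal's serial section series
#'
#' Runs the full per-animal quantification: selects the analysis section
#' (100 um rostral to the largest-area section), estimates and subtracts the
#' off-nucleus background from every section, computes the max-referenced
#' ipsilateral threshold Ti over the five sections centred on the area argmax,
#' measures the CTB-positive area and fraction, extracts size-filtered
#' ipsilateral patches and their DM-VL / O-I axis lengths, and — when the
#' section carries a monocular-segment annotation — computes the
#' mean-referenced contralateral threshold Tc, the flood-fill gap size and the
#' normalized dorsomedial-to-ventrolateral intensity profile.
#'
#' @param series A [section_series()] (raw intensities; backgrounds are
#'   estimated and subtracted internally).
#' @param alpha,beta Threshold coefficients for Ti and Tc.
#' @param min_patch_px Patch size cutoff (components must strictly exceed it).
#' @param contra If `TRUE` (default when a monocular region is present),
#'   also run the contralateral measurements.
#' @param profile If `TRUE`, attach the normalized intensity profile as a
#'   list-column.
#' @return One-row tibble with columns `analysis_index, dlgn_area_um2, Mi, Ti,
#'   ipsi_area_um2, ipsi_fraction_pct, n_patches, Q1Q2_um, DpVp_um,
#'   norm_dmvl_pct, P1P2_um, LM_um, norm_oi_pct, Mc, Tc, gap_area_um2,
#'   gap_fraction_pct, gap_valid` (+ list-column `profile`). Axis columns are
#'   `NA` when no patch survives the size filter; contralateral columns are
#'   `NA` when not measured.
#' @export
quantify_series <- function(series, alpha = 0.3, beta = 0.5,
                            min_patch_px = 150L, contra = NULL,
                            profile = TRUE) {
  stopifnot(inherits(series, "section_series"))
  idx <- select_analysis_section(series)
  argmax <- idx + 2L
  subbed <- series
  subbed$sections <- lapply(series$sections, function(s)
    subtract_background(s, estimate_background(s)))
  sec <- subbed$sections[[idx]]
  if (is.null(contra)) contra <- !is.null(sec$monocular_region)

  Mi <- compute_Mi(subbed, argmax)
  Ti <- threshold_Ti(Mi, alpha = alpha)
  pos <- ctb_positive_area(sec, Ti)
  supra <- sec$dlgn_mask & sec$intensity > Ti
  patches <- extract_patches(supra, min_size = min_patch_px)

  axes <- if (!patch_set_empty(patches)) measure_axis_lengths(sec, patches)
  else tibble::tibble(Q1Q2_um = NA_real_, DpVp_um = NA_real_,
                      norm_dmvl_pct = NA_real_, P1P2_um = NA_real_,
                      LM_um = NA_real_, norm_oi_pct = NA_real_)

  rec <- tibble::tibble(
    analysis_index = idx,
    dlgn_area_um2 = dlgn_area(sec),
    Mi = Mi, Ti = Ti,
    ipsi_area_um2 = pos$area_um2,
    ipsi_fraction_pct = pos$fraction_pct,
    n_patches = nrow(patches$components))
  rec <- dplyr::bind_cols(rec, axes)

  if (contra) {
    Mc <- compute_Mc(sec)
    Tc <- threshold_Tc(Mc, beta = beta)
    gap <- gap_size(sec, Tc)
    rec$Mc <- Mc; rec$Tc <- Tc
    rec$gap_area_um2 <- gap$gap_area_um2
    rec$gap_fraction_pct <- gap$gap_fraction_pct
    rec$gap_valid <- gap$valid
    if (profile) rec$profile <- list(intensity_profile(sec))
  } else {
    rec$Mc <- NA_real_; rec$Tc <- NA_real_
    rec$gap_area_um2 <- NA_real_; rec$gap_fraction_pct <- NA_real_
    rec$gap_valid <- NA
    if (profile) rec$profile <- list(NULL)
  }
  rec
}

#' Image-level phantom cohort presets
#'
#' Per-animal *image parameters* (true patch fractions) drawn from a printed
#' cohort's normal model, each rendered as a full phantom series — distinct
#' from the endpoint-level draws of [simulate_cohort()].
#'
#' @param name Preset name, e.g. `"Fig2A-images"`; `NULL` lists presets.
#' @keywords internal
image_preset_groups <- function(name) {
  presets <- list("Fig2A-images" = "Fig2A", "Fig4_P22-images" = "Fig4_P22")
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets))
    stop("unknown image preset '", name, "'", call. = FALSE)
  cohort_preset(presets[[name]])
}

#' Run a full quantification experiment
#'
#' Orchestrates phantom generation (or reading of section series from disk),
#' blind per-animal quantification, cohort aggregation and the gated group
#' statistics. Image analysis runs without access to group labels; labels are
#' joined only at the statistics stage. Per-animal failures (invalid gap,
#' missing landmarks, insufficient rostral coverage) are logged and excluded
#' with explicit counts, never silently dropped.
#'
#' @param config A named list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{preset}{image-level phantom preset name (e.g. `"Fig2A-images"`),
#'       or `NULL` when `series_dirs` is given.}
#'     \item{series_dirs}{named character vector of manifest directories
#'       (names = animal ids) to read with [read_series()].}
#'     \item{groups}{for `series_dirs` runs, a data frame `(animal, group)`.}
#'     \item{noise_sd, bias_amplitude}{phantom rendering options (preset runs;
#'       default 0).}
#'     \item{alpha, beta}{threshold coefficients (defaults 0.3, 0.5).}
#'     \item{min_patch_px}{patch size cutoff (default 150).}
#'     \item{seed}{integer seed driving cohort draws and phantom noise.}
#'   }
#' @return An object of class `dlgn_run`: list with `records` (per-animal
#'   QuantRecord tibble with group labels), `stats` (gated comparison tibble),
#'   `exclusions` (tibble of excluded animals with reasons), `truth`
#'   (per-animal generating parameters for phantom runs) and `provenance`
#'   (config echo, package version, config hash).
#' @export
run_quantification <- function(config) {
  config <- load_config(config)
  alpha <- config$alpha %||% 0.3
  beta <- config$beta %||% 0.5
  min_patch_px <- config$min_patch_px %||% 150L
  seed <- config$seed %||% 1L

  if (!is.null(config$preset)) {
    groups <- image_preset_groups(config$preset)
    draws <- simulate_cohort(groups, seed = seed)
    animals <- draws |>
      dplyr::mutate(animal_id = paste0(group, "_", animal),
                    patch_fraction = value / 100)
    made <- purrr::map(seq_len(nrow(animals)), function(i) {
      sp <- phantom_spec(patch_fraction = animals$patch_fraction[i],
                         noise_sd = config$noise_sd %||% 0,
                         bias_amplitude = config$bias_amplitude %||% 0,
                         seed = seed * 100L + i)
      make_series(sp)
    })
    series_list <- purrr::map(made, "series")
    names(series_list) <- animals$animal_id
    labels <- tibble::tibble(animal = animals$animal_id,
                             group = animals$group)
    # target = the cohort draw; rendered = the pixel-exact fraction of the
    # phantom actually rendered on the analysis section
    truth <- tibble::tibble(
      animal = animals$animal_id,
      group = animals$group,
      target_fraction_pct = animals$value,
      true_fraction_pct = purrr::map_dbl(
        made, ~ .x$truth$sections[[.x$truth$analysis_index]]$patch_fraction_pct))
  } else if (!is.null(config$series_dirs)) {
    series_list <- purrr::map(config$series_dirs, read_series)
    if (is.null(names(series_list)))
      names(series_list) <- paste0("animal_", seq_along(series_list))
    labels <- tibble::as_tibble(config$groups)
    truth <- NULL
  } else stop("config needs either `preset` or `series_dirs`", call. = FALSE)

  # Blind stage: quantify without group labels
  quant <- purrr::imap(series_list, function(s, id) {
    tryCatch(dplyr::mutate(quantify_series(
      s, alpha = alpha, beta = beta, min_patch_px = min_patch_px),
      animal = id, .before = 1),
      error = function(e) structure(conditionMessage(e), class = "quant_error",
                                    animal = id))
  })
  failed <- purrr::keep(quant, inherits, "quant_error")
  exclusions <- tibble::tibble(
    animal = purrr::map_chr(failed, ~ attr(.x, "animal")),
    reason = purrr::map_chr(failed, as.character))
  records <- dplyr::bind_rows(purrr::discard(quant, inherits, "quant_error"))
  # Gap-invalid sections are excluded from gap statistics, with a count
  if (nrow(records) > 0 && any(!is.na(records$gap_valid) & !records$gap_valid)) {
    inv <- records$animal[!is.na(records$gap_valid) & !records$gap_valid]
    exclusions <- dplyr::bind_rows(
      exclusions, tibble::tibble(animal = inv, reason = "gap connected to dLGN contour"))
  }
  records <- dplyr::left_join(records, labels, by = "animal") |>
    dplyr::relocate(group, .after = animal)

  stats <- if (nrow(records) > 0 && dplyr::n_distinct(records$group) >= 2) {
    compare_groups(records, value = "ipsi_fraction_pct", group = "group")
  } else tibble::tibble()

  structure(list(records = records, stats = stats, exclusions = exclusions,
                 truth = truth,
                 provenance = list(
                   config = config,
                   package_version = as.character(utils::packageVersion("dlgnquant")),
                   config_hash = rlang::hash(config),
                   n_excluded = nrow(exclusions))),
            class = "dlgn_run")
}

#' @export
print.dlgn_run <- function(x, ...) {
  cat("<dlgn_run> ", nrow(x$records), " animals quantified, ",
      nrow(x$exclusions), " excluded\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' Validate the pipeline against phantom ground truth
#'
#' For each seed, draws a true patch fraction and gap fraction uniformly from
#' the configured ranges, renders paired ipsilateral and contralateral phantom
#' series, runs the full quantification pipeline, and tabulates recovered
#' versus true values for the patch fraction, gap fraction and both normalized
#' axis lengths.
#'
#' @param config Named list (or YAML path) with optional fields `n_phantoms`
#'   (default 20), `seed` (default 1), `noise_frac` (noise SD as a fraction of
#'   the net label plateau; default 0.1), `patch_range_pct` (default
#'   `c(5, 30)`), `gap_range_pct` (default `c(5, 25)`), `alpha`, `beta`,
#'   `bias_amplitude`.
#' @return An object of class `dlgn_validation`: tibble
#'   `(phantom, quantity, truth, recovered, error)` with a bias/RMSE summary
#'   available through [glance.dlgn_validation()].
#' @export
run_phantom_validation <- function(config = list()) {
  config <- load_config(config)
  n <- config$n_phantoms %||% 20L
  seed <- config$seed %||% 1L
  noise_frac <- config$noise_frac %||% 0.1
  pr <- config$patch_range_pct %||% c(5, 30)
  gr <- config$gap_range_pct %||% c(5, 25)
  alpha <- config$alpha %||% 0.3
  beta <- config$beta %||% 0.5
  bias <- config$bias_amplitude %||% 0

  label <- 3000; bg <- 500
  noise_sd <- noise_frac * (label - bg)
  draws <- with_phantom_seed(seed, 1L, {
    tibble::tibble(phantom = seq_len(n),
                   patch_pct = stats::runif(n, pr[1], pr[2]),
                   gap_pct = stats::runif(n, gr[1], gr[2]))
  })

  rows <- purrr::map_dfr(seq_len(n), function(i) {
    sp_i <- phantom_spec(patch_fraction = draws$patch_pct[i] / 100,
                         label_intensity = label, background_level = bg,
                         noise_sd = noise_sd, bias_amplitude = bias,
                         seed = seed * 1000L + i)
    ms_i <- make_series(sp_i)
    rec_i <- quantify_series(ms_i$series, alpha = alpha, beta = beta,
                             profile = FALSE)
    tr_i <- ms_i$truth$sections[[ms_i$truth$analysis_index]]

    sp_c <- phantom_spec(gap_fraction = draws$gap_pct[i] / 100,
                         label_intensity = label, background_level = bg,
                         noise_sd = noise_sd, bias_amplitude = bias,
                         seed = seed * 1000L + 500L + i)
    ms_c <- make_series(sp_c)
    rec_c <- quantify_series(ms_c$series, alpha = alpha, beta = beta,
                             profile = FALSE)
    tr_c <- ms_c$truth$sections[[ms_c$truth$analysis_index]]

    tibble::tibble(
      phantom = i,
      quantity = c("patch_fraction_pct", "gap_fraction_pct",
                   "norm_dmvl_pct", "norm_oi_pct"),
      truth = c(tr_i$patch_fraction_pct, tr_c$gap_fraction_pct,
                tr_i$norm_dmvl, tr_i$norm_oi),
      recovered = c(rec_i$ipsi_fraction_pct, rec_c$gap_fraction_pct,
                    rec_i$norm_dmvl_pct, rec_i$norm_oi_pct))
  })
  out <- dplyr::mutate(rows, error = recovered - truth)
  class(out) <- c("dlgn_validation", class(out))
  out
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (f in c("alpha", "beta")) {
    if (!is.null(config[[f]]) && (config[[f]] <= 0 || config[[f]] >= 1))
      stop(f, " must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(config$min_patch_px) && config$min_patch_px < 0)
    stop("min_patch_px must be >= 0", call. = FALSE)
  config
}

`%||%` <- function(x, y) if (is.null(x)) y else x
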