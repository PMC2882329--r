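#' Plot a normalized intensity profile
#'
#' Normalized fluorescence against distance from the dorsomedial tip, the
#' standard presentation of dLGN tracer profiles; a reference line at 1 marks
#' the monocular-segment level.
#'
#' @param object A `dlgn_profile` from [intensity_profile()] or
#'   [vglut1_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dlgn_profile
#' @export
autoplot.dlgn_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = distance_um, y = normalized_intensity)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "#c0392b") +
    ggplot2::labs(x = "Distance from dorsomedial tip (µm)",
                  y = "Normalized intensity") +
    ggplot2::theme_classic()
}

#' Plot phantom recovery against ground truth
#'
#' Recovered versus true values per measured quantity, with the identity line.
#'
#' @param object A `dlgn_validation` from [run_phantom_validation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dlgn_validation
#' @export
autoplot.dlgn_validation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = truth, y = recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = "Ground truth (%)", y = "Recovered (%)") +
    ggplot2::theme_bw()
}

#' Plot per-animal fractions by group
#'
#' Group means with SD error bars over per-animal points, mirroring the usual
#' bar-and-scatter presentation of cohort summaries.
#'
#' @param data Data frame of per-animal values (e.g. [simulate_cohort()]
#'   output or `tidy()` of a [run_quantification()] result).
#' @param value,group Column names of the measurement and the group label.
#' @return A ggplot object.
#' @export
plot_cohort <- function(data, value = "value", group = "group") {
  s <- group_summaries(data, value = value, group = group)
  ggplot2::ggplot(s, ggplot2::aes(x = group, y = mean)) +
    ggplot2::geom_col(fill = "grey80", colour = "black", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sd, ymax = mean + sd),
                           width = 0.2) +
    ggplot2::geom_jitter(data = data,
                         ggplot2::aes(x = .data[[group]], y = .data[[value]]),
                         width = 0.08, size = 2, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "CTB-positive area / dLGN area (%)") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
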