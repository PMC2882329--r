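#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gated two-group comparison
#'
#' @param x A `dlgn_comparison` from [gated_compare()].
#' @param ... Unused.
#' @return One-row tibble `(test, statistic, df, p, gate_p, stars)`.
#' @method tidy dlgn_comparison
#' @export
tidy.dlgn_comparison <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  dplyr::mutate(out, stars = significance_stars(p))
}

#' @rdname tidy.dlgn_comparison
#' @method glance dlgn_comparison
#' @export
glance.dlgn_comparison <- function(x, ...) {
  gate <- attr(x, "gate")
  tibble::tibble(chosen_test = x$test, gate_statistic = gate$statistic,
                 gate_p = gate$p, p = x$p)
}

#' Tidy a quantification run
#'
#' @param x A `dlgn_run` from [run_quantification()].
#' @param ... Unused.
#' @return The per-animal QuantRecord tibble (without list-columns).
#' @method tidy dlgn_run
#' @export
tidy.dlgn_run <- function(x, ...) {
  rec <- x$records
  rec[!vapply(rec, is.list, logical(1))]
}

#' @rdname tidy.dlgn_run
#' @method glance dlgn_run
#' @export
glance.dlgn_run <- function(x, ...) {
  tibble::tibble(n_animals = nrow(x$records),
                 n_excluded = nrow(x$exclusions),
                 n_groups = dplyr::n_distinct(x$records$group),
                 config_hash = x$provenance$config_hash)
}

#' Summarise a phantom validation report
#'
#' @param x A `dlgn_validation` from [run_phantom_validation()].
#' @param ... Unused.
#' @return Tibble `(quantity, n, bias, rmse, max_abs_error)`.
#' @method glance dlgn_validation
#' @export
glance.dlgn_validation <- function(x, ...) {
  x |>
    dplyr::group_by(quantity) |>
    dplyr::summarise(n = dplyr::n(), bias = mean(error),
                     rmse = sqrt(mean(error^2)),
                     max_abs_error = max(abs(error)), .groups = "drop")
}

#' @rdname glance.dlgn_validation
#' @method tidy dlgn_validation
#' @export
tidy.dlgn_validation <- function(x, ...) tibble::as_tibble(unclass(x))
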