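#' Summarise groups from per-animal values
#'
#' @param data Data frame of per-animal measurements.
#' @param value,group Column names (strings) of the measured value and the
#'   group label.
#' @return Tibble `(group, mean, sd, n)`.
#' @export
group_summaries <- function(data, value = "value", group = "group") {
  stopifnot(is.data.frame(data))
  data |>
    dplyr::group_by(.data[[group]]) |>
    dplyr::summarise(mean = mean(.data[[value]]),
                     sd = stats::sd(.data[[value]]),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::rename(group = 1)
}

#' F-test variance gate between two groups
#'
#' Two-sided F-test comparing the two groups' variances, larger variance on
#' top, `p = 2 * min(tail, 1 - tail)` capped at 1. When the SDs do not differ
#' significantly (p >= alpha) the group means are compared with the unpaired
#' Student's t-test; otherwise with the unpaired Welch's t-test. Two groups
#' with zero SD have equal variances by definition and gate to Student.
#'
#' @param a,b One-row data frames (or named lists) with `mean`, `sd`, `n`.
#' @param alpha Gate level (default 0.05).
#' @return One-row tibble `(test, statistic, df1, df2, p, choice)` where
#'   `choice` is `"student"` or `"welch"`.
#' @export
f_variance_gate <- function(a, b, alpha = 0.05) {
  a <- as_group_summary(a); b <- as_group_summary(b)
  if (a$sd == 0 && b$sd == 0) {
    return(tibble::tibble(test = "f_gate", statistic = 1, df1 = a$n - 1L,
                          df2 = b$n - 1L, p = 1, choice = "student"))
  }
  if (a$sd >= b$sd) {
    fstat <- (a$sd / max(b$sd, .Machine$double.eps))^2
    df1 <- a$n - 1L; df2 <- b$n - 1L
  } else {
    fstat <- (b$sd / a$sd)^2
    df1 <- b$n - 1L; df2 <- a$n - 1L
  }
  tail <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  p <- min(1, 2 * min(tail, 1 - tail))
  tibble::tibble(test = "f_gate", statistic = fstat, df1 = df1, df2 = df2,
                 p = p, choice = if (p < alpha) "welch" else "student")
}

#' Two-sample t-test from group summaries
#'
#' Unpaired two-sided t-test computed from `(mean, sd, n)` summaries:
#' pooled-variance Student form (`df = n1 + n2 - 2`) or
#' Welch-Satterthwaite form (fractional df). Summary-statistic input lets the
#' printed group summaries of a publication be re-tested directly.
#'
#' @param a,b One-row data frames (or named lists) with `mean`, `sd`, `n`.
#' @param kind `"student"` or `"welch"`.
#' @return One-row tibble `(test, statistic, df, p)`.
#' @export
summary_t <- function(a, b, kind = c("student", "welch")) {
  kind <- match.arg(kind)
  a <- as_group_summary(a); b <- as_group_summary(b)
  if (a$n < 2 || b$n < 2) stop("each group needs n >= 2", call. = FALSE)
  md <- a$mean - b$mean
  if (kind == "student") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  tstat <- if (se == 0) 0 else md / se
  p <- if (se == 0 && md == 0) 1 else 2 * stats::pt(-abs(tstat), df)
  tibble::tibble(test = kind, statistic = tstat, df = df, p = p)
}

#' Two-sample t-test from raw per-animal values
#'
#' Identical to [summary_t()] applied to the groups' computed summaries.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @param kind `"student"` or `"welch"`.
#' @return One-row tibble `(test, statistic, df, p)`.
#' @export
sample_t <- function(a, b, kind = c("student", "welch")) {
  kind <- match.arg(kind)
  summary_t(list(mean = mean(a), sd = stats::sd(a), n = length(a)),
            list(mean = mean(b), sd = stats::sd(b), n = length(b)),
            kind = kind)
}

#' Variance-gated two-group comparison
#'
#' The study's two-group decision procedure: F-test the SDs, then compare the
#' means with Student's t (gate p >= alpha) or Welch's t (gate p < alpha).
#' Accepts either summary rows or a data frame of per-animal values.
#'
#' @param a,b Group summaries (`mean`, `sd`, `n`) or numeric vectors of raw
#'   values.
#' @param alpha Gate level (default 0.05).
#' @return An object of class `dlgn_comparison`: one-row tibble
#'   `(test, statistic, df, p, gate_p, gate_statistic)` plus a gate decision
#'   trail attribute.
#' @export
gated_compare <- function(a, b, alpha = 0.05) {
  if (is.numeric(a)) a <- list(mean = mean(a), sd = stats::sd(a), n = length(a))
  if (is.numeric(b)) b <- list(mean = mean(b), sd = stats::sd(b), n = length(b))
  gate <- f_variance_gate(a, b, alpha = alpha)
  res <- summary_t(a, b, kind = gate$choice)
  out <- dplyr::mutate(res, gate_p = gate$p, gate_statistic = gate$statistic)
  attr(out, "gate") <- gate
  class(out) <- c("dlgn_comparison", class(out))
  out
}

#' Tukey-Kramer pairwise comparisons for three or more groups
#'
#' Studentized-range test on all group pairs with the unequal-n Tukey-Kramer
#' standard error `sqrt(MSW/2 * (1/ni + 1/nj))`, where MSW is the pooled
#' within-group mean square with `N - k` degrees of freedom.
#'
#' @param data Data frame of per-animal values.
#' @param value,group Column names of the measurement and the group label.
#' @return Tibble with one row per pair:
#'   `(group1, group2, diff, statistic, df, p)`; `statistic` is the
#'   studentized range q.
#' @export
tukey_kramer <- function(data, value = "value", group = "group") {
  s <- group_summaries(data, value = value, group = group)
  k <- nrow(s)
  if (k < 3L)
    stop("Tukey-Kramer needs >= 3 groups; use gated_compare() for two",
         call. = FALSE)
  if (any(s$n < 2)) stop("every group needs n >= 2", call. = FALSE)
  N <- sum(s$n)
  msw <- sum((s$n - 1) * s$sd^2) / (N - k)
  pairs <- utils::combn(seq_len(k), 2)
  i1 <- pairs[1, ]; i2 <- pairs[2, ]
  diff <- s$mean[i1] - s$mean[i2]
  se <- sqrt(msw / 2 * (1 / s$n[i1] + 1 / s$n[i2]))
  q <- ifelse(se == 0, 0, abs(diff) / se)
  p <- ifelse(se == 0 & diff == 0, 1,
              stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE))
  tibble::tibble(group1 = s$group[i1], group2 = s$group[i2], diff = diff,
                 statistic = q, df = N - k, p = p)
}

#' Compare groups with the study's decision procedure
#'
#' Data-frame-first front door: two groups are routed through the F-gated
#' Student/Welch procedure, three or more through Tukey-Kramer.
#'
#' @param data Data frame of per-animal values.
#' @param value,group Column names of the measurement and the group label.
#' @param alpha Gate level for the two-group branch.
#' @return A tidy tibble of test results (see [gated_compare()] and
#'   [tukey_kramer()]).
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           alpha = 0.05) {
  s <- group_summaries(data, value = value, group = group)
  if (nrow(s) < 2L) stop("need at least two groups", call. = FALSE)
  if (nrow(s) == 2L) {
    res <- gated_compare(s[1, ], s[2, ], alpha = alpha)
    dplyr::mutate(res, group1 = s$group[1], group2 = s$group[2],
                  .before = 1)
  } else {
    tukey_kramer(data, value = value, group = group)
  }
}

#' Significance stars at the study's conventional levels
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `"**"` below 0.01, `"*"` below 0.05, `"N.S."`
#'   otherwise.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", .default = "N.S.")
}

as_group_summary <- function(x) {
  x <- as.list(x)
  if (!all(c("mean", "sd", "n") %in% names(x)))
    stop("a group summary needs mean, sd and n", call. = FALSE)
  if (x$n < 2) stop("each group needs n >= 2", call. = FALSE)
  if (x$sd < 0) stop("sd must be >= 0", call. = FALSE)
  x
}
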