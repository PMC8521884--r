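# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a repeated-measures ANOVA
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return One row per decomposition term with df, sums of squares, mean
#'   squares, and the F statistic and p-value on the time row.
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) {
  dplyr::mutate(
    x$ss,
    meansq = .data$sumsq / .data$df,
    statistic = ifelse(.data$term == "time", x$statistic, NA_real_),
    p.value = ifelse(.data$term == "time", x$p.value, NA_real_)
  )
}

#' @rdname tidy.rm_anova
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df_num = x$df_num,
                 df_den = x$df_den, p.value = x$p.value, n = x$n, k = x$k)
}

#' Tidy a single-marker analysis
#'
#' @param x A `marker_anova` object.
#' @param ... Unused.
#' @return `tidy()` returns the Tukey pairwise contrasts; `glance()` the
#'   one-row omnibus summary (the results-table row).
#' @method tidy marker_anova
#' @export
tidy.marker_anova <- function(x, ...) {
  dplyr::mutate(x$pairwise, condition = x$condition, marker = x$marker,
                .before = 1)
}

#' @rdname tidy.marker_anova
#' @method glance marker_anova
#' @export
glance.marker_anova <- function(x, ...) {
  glance_marker_anova_row(x)
}
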