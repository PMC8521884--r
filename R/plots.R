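# Presentation-layer plots: normalized trajectory panels and a results
# overview.  Plots are for inspection only; no statistic is computed here
# that the analysis functions do not already provide.

#' Normalized marker and MADRS trajectory plot
#'
#' Mean and standard-error trajectories over the three visit bins for a set
#' of markers (one condition), optionally overlaid with the MADRS
#' trajectory.  Each variable is min-max normalized to `[0, 1]` across its
#' own visit matrix so magnitudes are visually comparable; the underlying
#' tests always run on raw values.
#'
#' @param markers Tidy marker table.
#' @param madrs Optional MADRS table.
#' @param which_markers Markers to show (default the three headline ones).
#' @param condition Stimulus condition to plot (default `"neutral"`).
#' @param normalize Min-max normalize each variable (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(markers, madrs = NULL,
                              which_markers = c("overall_expressivity",
                                                "voice_percentage",
                                                "head_movement_mean"),
                              condition = "neutral", normalize = TRUE) {
  long_of <- function(vm, label) {
    if (normalize) vm <- minmax_normalize(vm)
    tidyr::pivot_longer(tibble::as_tibble(vm), -"subject_id",
                        names_to = "visit", values_to = "value") |>
      dplyr::group_by(.data$visit) |>
      dplyr::summarise(
        mean = mean(.data$value),
        se = sd(.data$value) / sqrt(dplyr::n()),
        .groups = "drop"
      ) |>
      dplyr::mutate(variable = label)
  }
  parts <- purrr::map_dfr(which_markers, function(mk) {
    d <- markers[markers$marker == mk & markers$stimulus_class == condition, ]
    long_of(visit_matrix(d), mk)
  })
  if (!is.null(madrs)) {
    parts <- dplyr::bind_rows(parts, long_of(madrs_visit_matrix(madrs), "MADRS"))
  }
  parts$visit <- factor(parts$visit, levels = visit_bins())
  ggplot2::ggplot(parts, ggplot2::aes(x = .data$visit, y = .data$mean,
                                      group = .data$variable,
                                      colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.1) +
    ggplot2::labs(x = NULL, y = if (normalize) "normalized value" else "value",
                  colour = NULL,
                  title = sprintf("Trajectories (%s stimuli)", condition)) +
    ggplot2::theme_minimal()
}

#' @method autoplot visit_matrix
#' @export
autoplot.visit_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"subject_id",
                              names_to = "visit", values_to = "value")
  long$visit <- factor(long$visit, levels = visit_bins())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$visit, y = .data$value,
                                     group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", linewidth = 1.2, colour = "#2166ac") +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}

#' @method autoplot marker_results
#' @export
autoplot.marker_results <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$marker <- factor(d$marker, levels = rev(marker_catalog()))
  d$condition <- factor(d$condition, levels = stimulus_classes())
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(pmax(.data$p_fdr, 1e-16)),
                                  y = .data$marker,
                                  colour = .data$direction,
                                  shape = .data$statistic_kind)) +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = 2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "-log10 FDR-adjusted p", y = NULL,
                  colour = "direction", shape = "statistic") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
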