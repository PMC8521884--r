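# Visit binning, per-bin aggregation with complete-case filtering, and the
# plot-only 0-1 normalisation.

visit_bins <- function() c("baseline", "week2", "week4")

#' Assign a study day to a visit bin
#'
#' Days 0–6 are baseline, days 7–21 average into the week-2 time point,
#' days 22–35 into the week-4 time point; later days are excluded.
#'
#' @param study_day Non-negative day(s) since treatment start.
#' @return Character vector in `{"baseline","week2","week4","excluded"}`.
#' @export
#' @examples
#' assign_bin(c(0, 7, 21, 22, 35, 36))
assign_bin <- function(study_day) {
  if (!is.numeric(study_day) || any(!is.finite(study_day)) || any(study_day < 0)) {
    abort("`study_day` must be non-negative finite numbers.",
          class = "dbm_bad_argument")
  }
  dplyr::case_when(
    study_day <= 6 ~ "baseline",
    study_day <= 21 ~ "week2",
    study_day <= 35 ~ "week4",
    TRUE ~ "excluded"
  )
}

#' Build a complete-case visit matrix for one variable
#'
#' Assigns each measurement to a visit bin, averages multiple measurements
#' within a subject-bin cell, and drops subjects missing any bin
#' (complete-case analysis).  The repeated-measures tests run on the
#' resulting subject-by-visit matrix.
#'
#' @param data Tidy data frame with `subject_id`, `study_day` and a value
#'   column.
#' @param value_col Name of the value column (default `"value"`).
#' @return A `visit_matrix` tibble with columns `subject_id`, `baseline`,
#'   `week2`, `week4`; attributes record `n_complete`, `n_total` and the
#'   dropped subject ids.
#' @export
#' @examples
#' d <- data.frame(subject_id = rep(c("a", "b"), each = 3),
#'                 study_day = rep(c(0, 14, 28), 2), value = rnorm(6))
#' visit_matrix(d)
visit_matrix <- function(data, value_col = "value") {
  needed <- c("subject_id", "study_day", value_col)
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    abort(sprintf("`data` lacks column(s): %s", paste(missing, collapse = ", ")),
          class = "dbm_bad_argument")
  }
  bins <- visit_bins()
  cells <- data |>
    dplyr::mutate(bin = assign_bin(.data$study_day)) |>
    dplyr::filter(.data$bin != "excluded", !is.na(.data[[value_col]])) |>
    dplyr::group_by(.data$subject_id, .data$bin) |>
    dplyr::summarise(value = mean(.data[[value_col]]), .groups = "drop")
  wide <- tidyr::pivot_wider(cells, names_from = "bin", values_from = "value")
  for (b in setdiff(bins, names(wide))) wide[[b]] <- NA_real_
  wide <- wide[c("subject_id", bins)]
  complete <- stats::complete.cases(wide[bins])
  dropped <- wide$subject_id[!complete]
  out <- wide[complete, ]
  if (nrow(out) < 2L) {
    have <- vapply(bins, function(b) sum(!is.na(wide[[b]])), integer(1))
    abort(sprintf(
      "complete-case filtering leaves %d subject(s); need >= 2. Subjects per bin: %s.",
      nrow(out), paste(sprintf("%s=%d", bins, have), collapse = ", ")),
      class = "dbm_insufficient_n")
  }
  structure(out, class = c("visit_matrix", class(out)),
            n_complete = nrow(out),
            n_total = length(unique(data$subject_id)),
            dropped = dropped)
}

#' Visit matrix of MADRS scores
#'
#' @param madrs MADRS table with `subject_id`, `study_day`, `madrs`.
#' @return A `visit_matrix` (see [visit_matrix()]).
#' @export
madrs_visit_matrix <- function(madrs) {
  visit_matrix(madrs, value_col = "madrs")
}

vm_values <- function(x) {
  m <- as.matrix(x[visit_bins()])
  rownames(m) <- x$subject_id
  m
}

#' Min-max normalise a visit matrix to \[0, 1\]
#'
#' Rescales all cells by the global minimum and maximum of the matrix —
#' used only to overlay markers and MADRS on a common scale in trajectory
#' plots.  By contract the statistical tests always run on raw values;
#' normalisation never precedes an ANOVA.
#'
#' @param x A `visit_matrix`.
#' @return The matrix with all cells rescaled to `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  m <- vm_values(x)
  rng <- range(m)
  if (diff(rng) == 0) {
    abort("matrix is constant: min-max normalisation undefined.",
          class = "dbm_zero_variance")
  }
  for (b in visit_bins()) x[[b]] <- (x[[b]] - rng[1]) / diff(rng)
  x
}
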