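# Extraction stage: raw per-response signals -> the tidy 17-marker table.

#' All 17 markers for one stimulus response
#'
#' Computes the 13 facial markers and 3 movement markers from a frame table
#' (after the quality gate) and the voice percentage from the amplitude
#' trace via [detect_speech()].
#'
#' @param frames Frame table with AU, pose and quality columns.
#' @param audio An `amplitude_series` or numeric vector.
#' @param sample_rate Audio sample rate (ignored when `audio` carries one).
#' @param emotion_map AU prototype map.
#' @param min_confidence Frame quality gate (default 0.70).
#' @return Tibble `(marker, value)` with 17 rows in catalog order.
#' @export
compute_response_markers <- function(frames, audio, sample_rate = NULL,
                                     emotion_map = default_emotion_map(),
                                     min_confidence = 0.70) {
  fm <- facial_markers(frames, emotion_map, min_confidence)
  mm <- movement_markers(frames, min_confidence)
  segs <- detect_speech(audio, sample_rate)
  vm <- tibble::tibble(marker = "voice_percentage",
                       value = voice_percentage(segs))
  out <- dplyr::bind_rows(fm, mm, vm)
  out[match(marker_catalog(), out$marker), ]
}

#' Extract the tidy marker table from rendered assessments
#'
#' Computes the 17 markers for every stimulus response, then averages within
#' subject, study day and stimulus valence class (markers are computed
#' within-stimulus and then averaged, matching a per-condition results
#' layout).
#'
#' @param assessments Rendered assessment tibble (e.g.
#'   `simulate_cohort(..., render = TRUE)$assessments`): one row per
#'   stimulus response with `subject_id`, `study_day`, `valence_class`,
#'   list-columns `frames` and `audio`, and `sample_rate`.
#' @inheritParams compute_response_markers
#' @return Tidy marker table `(subject_id, study_day, stimulus_class,
#'   marker, value)`.
#' @export
extract_markers <- function(assessments,
                            emotion_map = default_emotion_map(),
                            min_confidence = 0.70) {
  needed <- c("subject_id", "study_day", "valence_class", "frames", "audio")
  missing <- setdiff(needed, names(assessments))
  if (length(missing)) {
    abort(sprintf("`assessments` lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "dbm_bad_argument")
  }
  per_response <- purrr::map_dfr(seq_len(nrow(assessments)), function(i) {
    row <- assessments[i, ]
    sr <- if ("sample_rate" %in% names(assessments)) row$sample_rate else NULL
    mk <- compute_response_markers(row$frames[[1]], row$audio[[1]],
                                   sample_rate = sr,
                                   emotion_map = emotion_map,
                                   min_confidence = min_confidence)
    dplyr::mutate(mk, subject_id = row$subject_id, study_day = row$study_day,
                  stimulus_class = row$valence_class, .before = 1)
  })
  per_response |>
    dplyr::group_by(.data$subject_id, .data$study_day,
                    .data$stimulus_class, .data$marker) |>
    dplyr::summarise(value = mean(.data$value, na.rm = FALSE), .groups = "drop") |>
    dplyr::arrange(.data$subject_id, .data$study_day,
                   .data$stimulus_class, .data$marker)
}
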