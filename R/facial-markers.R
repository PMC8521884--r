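# Facial markers: per-frame emotion scoring from AU presence/intensity,
# emotion counts and intensities, and the overall expressivity composite.

#' Quality-gate a frame table
#'
#' Keeps frames with `success == 1` and `confidence >= min_confidence`
#' (default 0.70).  All facial and movement markers are computed on gated
#' frames only; when nothing survives, markers are reported missing (`NA`),
#' never zero.
#'
#' @param frames Frame table with `success` and `confidence` columns.
#' @param min_confidence Minimum tracking confidence (default 0.70).
#' @return The retained rows, with `"n_total"` and `"n_retained"` attributes.
#' @export
filter_valid_frames <- function(frames, min_confidence = 0.70) {
  if (!all(c("success", "confidence") %in% names(frames))) {
    abort("`frames` must have `success` and `confidence` columns.",
          class = "dbm_bad_argument")
  }
  keep <- frames$success == 1 & frames$confidence >= min_confidence
  out <- frames[keep, , drop = FALSE]
  attr(out, "n_total") <- nrow(frames)
  attr(out, "n_retained") <- sum(keep)
  out
}

# n x 6 matrices of AU-match fraction and mean constituent intensity.
emotion_score_matrices <- function(frames, emotion_map = default_emotion_map()) {
  check_emotion_map(emotion_map)
  emo <- names(emotion_map)
  n <- nrow(frames)
  match_m <- matrix(0, n, length(emo), dimnames = list(NULL, emo))
  int_m <- match_m
  for (e in emo) {
    rc <- au_col(emotion_map[[e]], "r")
    cc <- au_col(emotion_map[[e]], "c")
    missing <- setdiff(c(rc, cc), names(frames))
    if (length(missing)) {
      abort(sprintf("frame table lacks AU columns: %s",
                    paste(missing, collapse = ", ")),
            class = "dbm_bad_argument")
    }
    match_m[, e] <- rowMeans(as.matrix(frames[cc]))
    int_m[, e] <- rowMeans(as.matrix(frames[rc]))
  }
  list(match = match_m, intensity = int_m)
}

#' Per-frame emotion match and intensity scores
#'
#' For every frame and basic emotion: the fraction of the emotion's
#' constituent AUs flagged present (`match`, in `[0, 1]`) and the mean of
#' their intensities (`intensity`, on the 0–5 scale).
#'
#' @param frames Frame table with `AUxx_c` and `AUxx_r` columns.
#' @param emotion_map AU prototype map (default [default_emotion_map()]).
#' @return Tidy tibble `(frame, emotion, match, intensity)`.
#' @export
frame_emotion_scores <- function(frames, emotion_map = default_emotion_map()) {
  sc <- emotion_score_matrices(frames, emotion_map)
  frame_id <- if ("frame" %in% names(frames)) frames$frame else seq_len(nrow(frames))
  tidyr::pivot_longer(
    dplyr::bind_cols(
      tibble::tibble(frame = frame_id),
      tibble::as_tibble(sc$match)
    ),
    -"frame", names_to = "emotion", values_to = "match"
  ) |>
    dplyr::mutate(intensity = as.vector(t(sc$intensity)))
}

#' Label each frame with its most probable emotion
#'
#' Per frame, the emotion with the highest AU-match fraction is selected,
#' provided the fraction reaches `match_threshold` (default 0.5); otherwise
#' the frame is labelled `"none"`.  Exact match ties are broken by the
#' number of active constituent AUs (the prototype explaining more of the
#' observed activation wins — this resolves the fear/surprise subsumption
#' case deterministically), then by higher per-frame intensity, then by the
#' fixed order [emotion_tie_order()].
#'
#' @inheritParams frame_emotion_scores
#' @param match_threshold Minimum AU-match fraction to assign any label.
#' @return Character vector of labels, one per frame.
#' @export
#' @examples
#' fr <- simulate_au_frames(1, expressivity_level = 3,
#'                          episodes = c(happiness = 1), seed = 1)
#' table(frame_emotion_label(fr))
frame_emotion_label <- function(frames, emotion_map = default_emotion_map(),
                                match_threshold = 0.5) {
  sc <- emotion_score_matrices(frames, emotion_map)
  ord <- intersect(emotion_tie_order(), colnames(sc$match))
  m <- sc$match[, ord, drop = FALSE]
  r <- sc$intensity[, ord, drop = FALSE]
  if (nrow(m) == 0L) return(character(0))
  # lexicographic (match, n active AUs, intensity, tie order) via a
  # composite key: match increments are multiples of >= 1/42, active-AU
  # counts <= 7 scaled below that, intensities <= 5 below the count step,
  # and the order term below numeric noise.
  sizes <- vapply(emotion_map[ord], length, integer(1))
  n_active <- sweep(m, 2L, sizes, "*")
  prio <- matrix(rep(seq(length(ord), 1), each = nrow(m)), nrow = nrow(m))
  key <- m + n_active * 1e-3 + r * 1e-5 + prio * 1e-9
  best <- max.col(key, ties.method = "first")
  lab <- ord[best]
  lab[m[cbind(seq_len(nrow(m)), best)] < match_threshold] <- "none"
  lab
}

#' Emotion count marker
#'
#' Fraction of quality-gated frames labelled with the given emotion — the
#' per-frame "most probable emotion" selections pooled over the response.
#' The six counts plus the unlabelled fraction always sum to one.
#'
#' @inheritParams frame_emotion_label
#' @param emotion One of the six basic emotion names.
#' @param min_confidence Quality gate passed to [filter_valid_frames()].
#' @return Fraction in `[0, 1]`, or `NA` if no frame survives the gate.
#' @export
emotion_count <- function(frames, emotion, emotion_map = default_emotion_map(),
                          min_confidence = 0.70, match_threshold = 0.5) {
  stopifnot(emotion %in% names(emotion_map))
  valid <- filter_valid_frames(frames, min_confidence)
  if (nrow(valid) == 0L) return(NA_real_)
  mean(frame_emotion_label(valid, emotion_map, match_threshold) == emotion)
}

#' Emotion intensity marker
#'
#' Mean over quality-gated frames of the emotion's per-frame intensity (the
#' mean intensity of its constituent AUs), on the 0–5 AU scale.  All frames
#' contribute, not only frames labelled with the emotion.
#'
#' @inheritParams emotion_count
#' @return Mean intensity in `[0, 5]`, or `NA` if no frame survives.
#' @export
emotion_intensity <- function(frames, emotion, emotion_map = default_emotion_map(),
                              min_confidence = 0.70) {
  stopifnot(emotion %in% names(emotion_map))
  valid <- filter_valid_frames(frames, min_confidence)
  if (nrow(valid) == 0L) return(NA_real_)
  sc <- emotion_score_matrices(valid, emotion_map)
  mean(sc$intensity[, emotion])
}

#' Overall facial expressivity
#'
#' Composite facial-activity score: per frame, the six emotion intensities
#' are summed; the marker is the mean of that sum over quality-gated frames
#' (range 0–30).  By linearity it equals the sum of the six
#' [emotion_intensity()] markers.
#'
#' @inheritParams emotion_count
#' @param from `"emotions"` (default) sums the six per-frame emotion
#'   intensities; `"aus"` instead averages the raw AU intensity columns per
#'   frame — an alternative composite kept for comparison.
#' @return Composite score, or `NA` if no frame survives.
#' @export
overall_expressivity <- function(frames, emotion_map = default_emotion_map(),
                                 min_confidence = 0.70,
                                 from = c("emotions", "aus")) {
  from <- match.arg(from)
  valid <- filter_valid_frames(frames, min_confidence)
  if (nrow(valid) == 0L) return(NA_real_)
  if (from == "emotions") {
    sc <- emotion_score_matrices(valid, emotion_map)
    mean(rowSums(sc$intensity))
  } else {
    rc <- intersect(au_col(openface_au_ids(), "r"), names(valid))
    mean(rowMeans(as.matrix(valid[rc])))
  }
}

#' All 13 facial markers for one response
#'
#' @inheritParams emotion_count
#' @return Tibble `(marker, value)` with six counts, six intensities and
#'   overall expressivity; values are `NA` when no frame passes the gate.
#' @export
facial_markers <- function(frames, emotion_map = default_emotion_map(),
                           min_confidence = 0.70, match_threshold = 0.5) {
  valid <- filter_valid_frames(frames, min_confidence)
  emo <- names(emotion_map)
  if (nrow(valid) == 0L) {
    return(tibble::tibble(
      marker = c(paste0(emo, "_count"), paste0(emo, "_intensity"),
                 "overall_expressivity"),
      value = NA_real_
    ))
  }
  sc <- emotion_score_matrices(valid, emotion_map)
  labels <- frame_emotion_label(valid, emotion_map, match_threshold)
  counts <- vapply(emo, function(e) mean(labels == e), numeric(1))
  intens <- colMeans(sc$intensity)[emo]
  tibble::tibble(
    marker = c(paste0(emo, "_count"), paste0(emo, "_intensity"),
               "overall_expressivity"),
    value = c(counts, intens, sum(intens))
  )
}
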