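# Marker catalog and the AU -> emotion prototype map.

#' Default facial action unit map for the six basic emotions
#'
#' Prototype action-unit (AU) sets for the six basic emotions, following the
#' conventional EMFACS/Ekman prototypes: happiness \{6, 12\}, sadness
#' \{1, 4, 15\}, surprise \{1, 2, 5, 26\}, fear \{1, 2, 4, 5, 7, 20, 26\},
#' anger \{4, 5, 7, 23\}, disgust \{9, 15\}.  The map is declarative: pass a
#' modified copy to any facial-marker function to swap prototypes.
#'
#' Note that the fear prototype strictly contains the surprise prototype, so
#' a frame with all fear AUs active matches both at fraction 1; ties are
#' resolved by per-frame intensity and then by [emotion_tie_order()].
#'
#' @return Named list mapping emotion name to an integer vector of AU ids.
#' @seealso [frame_emotion_label()], [facial_markers()]
#' @export
#' @examples
#' default_emotion_map()$happiness
default_emotion_map <- function() {
  list(
    happiness = c(6L, 12L),
    sadness   = c(1L, 4L, 15L),
    surprise  = c(1L, 2L, 5L, 26L),
    fear      = c(1L, 2L, 4L, 5L, 7L, 20L, 26L),
    anger     = c(4L, 5L, 7L, 23L),
    disgust   = c(9L, 15L)
  )
}

#' Fixed emotion order used to break exact labelling ties
#'
#' When two emotions tie on AU-match fraction, active-AU count and
#' per-frame intensity, the earlier emotion in this order wins.  Emotions
#' with larger (more specific) AU prototypes come first, so fear precedes
#' surprise, whose prototype it subsumes.
#'
#' @return Character vector of the six emotion names.
#' @export
emotion_tie_order <- function() {
  c("fear", "surprise", "anger", "sadness", "disgust", "happiness")
}

emotion_names <- function() names(default_emotion_map())

#' The 17-marker catalog
#'
#' The fixed set of digital markers the pipeline computes per assessment:
#' voice percentage, per-emotion intensity and count for the six basic
#' emotions, overall expressivity, and the three head-movement markers.
#' The order is the canonical row order of results tables.
#'
#' @return Character vector of 17 marker names.
#' @export
#' @examples
#' marker_catalog()
marker_catalog <- function() {
  emo <- sort(emotion_names())
  c(
    "voice_percentage",
    as.vector(rbind(paste0(emo, "_intensity"), paste0(emo, "_count"))),
    "overall_expressivity",
    "head_movement_mean",
    "head_movement_sd",
    "head_pose_change_mean"
  )
}

# AU ids emitted by the OpenFace intensity channel; the synthetic generator
# and the readers/writers use this fixed column set.
openface_au_ids <- function() {
  c(1L, 2L, 4L, 5L, 6L, 7L, 9L, 10L, 12L, 14L, 15L, 17L, 20L, 23L, 25L, 26L, 45L)
}

au_col <- function(ids, channel = c("r", "c")) {
  channel <- match.arg(channel)
  sprintf("AU%02d_%s", ids, channel)
}

stimulus_classes <- function() c("neutral", "positive", "negative")

check_emotion_map <- function(map, au_ids = openface_au_ids()) {
  if (!is.list(map) || length(map) != 6L || is.null(names(map))) {
    abort("`emotion_map` must be a named list of six AU sets.",
          class = "dbm_bad_argument")
  }
  missing <- setdiff(unlist(map), au_ids)
  if (length(missing)) {
    abort(sprintf("emotion map references AUs absent from the column set: %s",
                  paste(missing, collapse = ", ")),
          class = "dbm_bad_argument")
  }
  invisible(map)
}
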