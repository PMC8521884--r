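# Voice marker: energy-threshold speech/non-speech segmentation and the
# voice-percentage ratio.

#' Segment an amplitude trace into speech and non-speech
#'
#' A self-contained energy detector with Praat-convention defaults: the
#' signal is framed into non-overlapping `window_s` windows (10 ms), window
#' log-energy is thresholded at `max - dynamic_range_db` dB (25 dB below the
#' loudest window, so the rule is invariant to overall gain), interior
#' silent gaps shorter than `min_silence_s` (0.3 s) are bridged, and
#' sounding runs shorter than `min_sounding_s` (0.1 s) are discarded.
#'
#' @param x An `amplitude_series` (see [simulate_audio()]) or numeric vector.
#' @param sample_rate Samples per second (ignored if `x` carries its own).
#' @param window_s Analysis window in seconds (default 0.01).
#' @param dynamic_range_db Threshold below the maximum window energy, in dB.
#' @param min_silence_s Interior silent gaps shorter than this are bridged.
#' @param min_sounding_s Sounding runs shorter than this are discarded.
#' @return A `speech_segments` tibble `(start_s, end_s)` with a
#'   `"total_duration_s"` attribute.  Digital silence yields zero segments.
#' @export
#' @examples
#' a <- simulate_audio(0.5, duration_s = 8, seed = 1)
#' detect_speech(a)
detect_speech <- function(x, sample_rate = NULL, window_s = 0.01,
                          dynamic_range_db = 25, min_silence_s = 0.3,
                          min_sounding_s = 0.1) {
  if (inherits(x, "amplitude_series")) {
    sample_rate <- x$sample_rate
    x <- x$samples
  }
  if (is.null(sample_rate) || sample_rate <= 0) {
    abort("`sample_rate` must be positive.", class = "dbm_bad_argument")
  }
  if (!is.numeric(x) || length(x) == 0L) {
    abort("amplitude series must be a non-empty numeric vector.",
          class = "dbm_bad_argument")
  }
  win <- max(1L, round(window_s * sample_rate))
  nw <- length(x) %/% win
  if (nw < 1L) {
    abort("signal shorter than one analysis window.", class = "dbm_too_short")
  }
  total_s <- length(x) / sample_rate
  energy <- colMeans(matrix(x[seq_len(nw * win)]^2, nrow = win))

  empty <- tibble::tibble(start_s = numeric(), end_s = numeric())
  segs <- if (max(energy) <= 0) {
    empty
  } else {
    db <- 10 * log10(energy)
    db[!is.finite(db)] <- -Inf
    sounding <- db >= max(db) - dynamic_range_db

    # bridge interior silent gaps shorter than min_silence_s
    r <- rle(sounding)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    interior <- !r$values & seq_along(r$values) > 1L &
      seq_along(r$values) < length(r$values)
    for (i in which(interior & r$lengths * window_s < min_silence_s)) {
      sounding[starts[i]:ends[i]] <- TRUE
    }
    # discard sounding runs shorter than min_sounding_s
    r <- rle(sounding)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths * window_s < min_sounding_s)) {
      sounding[starts[i]:ends[i]] <- FALSE
    }
    r <- rle(sounding)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) {
      empty
    } else {
      tibble::tibble(
        start_s = (starts[keep] - 1L) * window_s,
        end_s = pmin(ends[keep] * window_s, total_s)
      )
    }
  }
  structure(segs,
            class = c("speech_segments", class(segs)),
            total_duration_s = total_s,
            params = list(window_s = window_s,
                          dynamic_range_db = dynamic_range_db,
                          min_silence_s = min_silence_s,
                          min_sounding_s = min_sounding_s))
}

#' Voice percentage
#'
#' Total speech time divided by total response time — the fraction of the
#' response spent speaking rather than in silence, bounded in `[0, 1]`.
#'
#' @param segments A `speech_segments` object from [detect_speech()], or a
#'   data frame of `(start_s, end_s)` intervals.
#' @param total_duration_s Total duration; taken from `segments` when it
#'   carries one.
#' @return Fraction of time with speech.
#' @export
#' @examples
#' voice_percentage(data.frame(start_s = c(0, 5), end_s = c(2, 7)),
#'                  total_duration_s = 10)
voice_percentage <- function(segments, total_duration_s = NULL) {
  total_duration_s <- total_duration_s %||% attr(segments, "total_duration_s")
  if (is.null(total_duration_s) || !is.finite(total_duration_s) ||
      total_duration_s <= 0) {
    abort("`total_duration_s` must be a positive number.",
          class = "dbm_bad_argument")
  }
  if (nrow(segments) == 0L) return(0)
  if (any(segments$end_s < segments$start_s)) {
    abort("segments must have end_s >= start_s.", class = "dbm_bad_argument")
  }
  min(sum(segments$end_s - segments$start_s) / total_duration_s, 1)
}
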