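# Affective stimulus pipeline: valence normalisation, three-way
# classification with buffer zones, sequence assembly with a no-repeat
# constraint, and the minimum-speech validity rule.

#' Standardize raw valence scores
#'
#' Z-scores a vector of population-mean valence ratings using the population
#' standard deviation convention (divisor `n`), so the output has mean 0 and
#' SD exactly 1.  At pool sizes of several hundred images the population vs
#' sample convention is immaterial; the choice is fixed here so class
#' thresholds are reproducible.
#'
#' @param raw Numeric vector of raw valence means (at least two distinct
#'   values).
#' @return Numeric vector of z-scores.
#' @export
#' @examples
#' zscore_valences(c(1, 2, 3))
zscore_valences <- function(raw) {
  if (!is.numeric(raw) || length(raw) < 2L || anyNA(raw)) {
    abort("`raw` must be a numeric vector of length >= 2 without NAs.",
          class = "dbm_bad_argument")
  }
  mu <- mean(raw)
  sd_pop <- sqrt(mean((raw - mu)^2))
  if (sd_pop == 0) {
    abort("valence scores are constant: z-scoring undefined (zero variance).",
          class = "dbm_zero_variance")
  }
  (raw - mu) / sd_pop
}

#' Classify a standardized valence score
#'
#' Three-class assignment with buffer zones: `|z| <= neutral_band` is
#' neutral, `z >= outer_threshold` positive, `z <= -outer_threshold`
#' negative, and anything in between is `buffer` — images deliberately left
#' unused so the classes are well separated.  Defaults are the protocol
#' constants 0.5 and 1.5; the negative rule is the mirror image of the
#' positive one.
#'
#' @param z Numeric vector of finite z-scores.
#' @param neutral_band Half-width of the closed neutral band (default 0.5).
#' @param outer_threshold Inclusive threshold for the positive/negative
#'   classes (default 1.5).
#' @return Character vector in `{"negative","neutral","positive","buffer"}`.
#' @export
#' @examples
#' classify_valence(c(0, 1, 1.6, -2))
classify_valence <- function(z, neutral_band = 0.5, outer_threshold = 1.5) {
  if (!is.numeric(z) || length(z) == 0L || any(!is.finite(z))) {
    abort("`z` must be a non-empty numeric vector of finite values.",
          class = "dbm_bad_argument")
  }
  if (neutral_band <= 0 || outer_threshold <= neutral_band) {
    abort("need 0 < neutral_band < outer_threshold.", class = "dbm_bad_argument")
  }
  dplyr::case_when(
    abs(z) <= neutral_band ~ "neutral",
    z >= outer_threshold ~ "positive",
    z <= -outer_threshold ~ "negative",
    TRUE ~ "buffer"
  )
}

#' Prepare a stimulus pool from raw valence ratings
#'
#' @param pool Data frame with columns `image_id` and `raw_valence`.
#' @inheritParams classify_valence
#' @return A tibble with added `z_valence` and `valence_class` columns.
#' @export
prepare_stimulus_pool <- function(pool, neutral_band = 0.5, outer_threshold = 1.5) {
  if (!all(c("image_id", "raw_valence") %in% names(pool))) {
    abort("`pool` needs columns `image_id` and `raw_valence`.",
          class = "dbm_bad_argument")
  }
  if (anyDuplicated(pool$image_id)) {
    abort("duplicate image_id in stimulus pool.", class = "dbm_bad_argument")
  }
  pool <- tibble::as_tibble(pool)
  pool$z_valence <- zscore_valences(pool$raw_valence)
  pool$valence_class <- classify_valence(pool$z_valence, neutral_band, outer_threshold)
  pool
}

#' Simulate an OASIS-like stimulus pool
#'
#' Draws raw valence means from a truncated normal on the 1–7 rating scale
#' and classifies them.  A pool of 900 images with the default thresholds
#' leaves roughly 60 images in each outer class and ~340 neutral images —
#' enough to sequence a multi-visit study without repetition.
#'
#' @param n_images Pool size (default 900).
#' @param seed Integer seed; required for a reproducible pool.
#' @inheritParams classify_valence
#' @return A prepared stimulus pool tibble.
#' @export
simulate_stimulus_pool <- function(n_images = 900, seed = NULL,
                                   neutral_band = 0.5, outer_threshold = 1.5) {
  assert_scalar_number(n_images, "n_images", min = 10)
  raw <- with_seed_if(seed, rtrunc_norm(n_images, mean = 4, sd = 1.2, lower = 1, upper = 7))
  prepare_stimulus_pool(
    tibble::tibble(
      image_id = sprintf("img%04d", seq_len(n_images)),
      raw_valence = raw
    ),
    neutral_band, outer_threshold
  )
}

sequence_class_pattern <- function() {
  c(rep(c("neutral", "positive", "neutral", "negative"), 3L), "neutral")
}

#' Assemble one 13-image assessment sequence
#'
#' Builds the fixed valence pattern N P N X N P N X N P N X N (7 neutral,
#' 3 positive, 3 negative; X = negative), drawing images uniformly at random
#' from the pool while excluding everything in `history`, so no image is
#' ever repeated across a subject's assessments.  The neutral padding keeps
#' positive and negative images from ever being adjacent.
#'
#' @param pool A prepared stimulus pool (see [prepare_stimulus_pool()]).
#' @param history Character vector of image ids already shown.
#' @param seed Optional integer seed for the random draw.
#' @return A tibble `(position, image_id, valence_class)` with 13 rows.
#' @export
build_sequence <- function(pool, history = character(), seed = NULL) {
  pattern <- sequence_class_pattern()
  need <- table(pattern)
  unused <- pool[!pool$image_id %in% history, , drop = FALSE]
  with_seed_if(seed, {
    picks <- lapply(names(need), function(cl) {
      avail <- unused$image_id[unused$valence_class == cl]
      if (length(avail) < need[[cl]]) {
        abort(
          sprintf(
            "stimulus pool exhausted: need %d unused %s image(s), only %d left.",
            need[[cl]], cl, length(avail)
          ),
          class = "dbm_pool_exhausted", depleted_class = cl
        )
      }
      sample(avail, need[[cl]])
    })
    names(picks) <- names(need)
    counters <- setNames(rep(0L, length(need)), names(need))
    ids <- character(length(pattern))
    for (i in seq_along(pattern)) {
      cl <- pattern[i]
      counters[[cl]] <- counters[[cl]] + 1L
      ids[i] <- picks[[cl]][counters[[cl]]]
    }
    tibble::tibble(
      position = seq_along(pattern),
      image_id = ids,
      valence_class = pattern
    )
  })
}

#' Build the full stimulus manifest for a simulated study
#'
#' Calls [build_sequence()] once per subject and assessment day, threading a
#' per-subject history so no subject ever sees the same image twice.
#'
#' @param pool Prepared stimulus pool.
#' @param subject_ids Character vector of subject ids.
#' @param study_days Integer vector of assessment days.
#' @param seed Integer seed.
#' @return Tibble `(subject_id, study_day, position, image_id, valence_class)`.
#' @export
simulate_study_sequences <- function(pool, subject_ids, study_days, seed = NULL) {
  with_seed_if(seed, {
    purrr::map_dfr(subject_ids, function(sid) {
      history <- character()
      purrr::map_dfr(study_days, function(day) {
        seq_tbl <- build_sequence(pool, history)
        history <<- c(history, seq_tbl$image_id)
        dplyr::mutate(seq_tbl, subject_id = sid, study_day = day, .before = 1)
      })
    })
  })
}

#' Minimum-speech validity rule for one stimulus response
#'
#' A response is valid when the participant spoke for at least
#' `min_speech_s` seconds (protocol default 10 s per image).
#'
#' @param speech_duration_s Non-negative speech duration(s) in seconds.
#' @param min_speech_s Threshold in seconds (default 10).
#' @return Logical vector: `TRUE` for pass.
#' @export
#' @examples
#' validate_response(c(10, 9.99))
validate_response <- function(speech_duration_s, min_speech_s = 10) {
  if (!is.numeric(speech_duration_s) || any(is.na(speech_duration_s)) ||
      any(speech_duration_s < 0)) {
    abort("`speech_duration_s` must be non-negative numbers.",
          class = "dbm_bad_argument")
  }
  speech_duration_s >= min_speech_s
}
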