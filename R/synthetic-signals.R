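# Frame-level synthetic signals: AU tables in the OpenFace dialect, head
# pose random walks, and amplitude traces with a known speech schedule.
# These emulate the raw per-response inputs of the extraction stage so every
# downstream marker has a controllable ground truth.

#' Simulate a per-frame action-unit table
#'
#' Generates an OpenFace-dialect frame table for one stimulus response.
#' Outside emotion episodes every AU idles at a low baseline intensity
#' (|N(0, 0.05 * expressivity_level)|); during an episode the constituent
#' AUs of that emotion sit at `expressivity_level` plus noise, clipped to
#' the 0–5 AU intensity scale.  Presence flags are intensity >
#' `activation_threshold` (default 1.0), the same rule the facial-marker
#' stage assumes.  With `expressivity_level = 0` the table is exactly blank.
#'
#' Episodes are laid out as contiguous blocks from the first frame in the
#' order given, so the realized schedule (returned as the
#' `"episode_schedule"` attribute, one label per frame) is known exactly and
#' downstream emotion counts can be checked against it.
#'
#' @param duration_s Positive response duration in seconds.
#' @param fps Frames per second (default 30).
#' @param expressivity_level Mean active-AU intensity on the 0–5 scale.
#' @param episodes Named numeric vector of per-emotion frame fractions
#'   (summing to at most 1), or `NULL` for a blank schedule.
#' @param activation_threshold Intensity above which the presence flag is 1.
#' @param noise_sd SD of intensity noise during episodes (default 0.2).
#' @param failure_rate Fraction of frames marked as tracking failures
#'   (`success = 0`, default 0).
#' @param seed Optional integer seed.
#' @return Tibble with `frame`, `timestamp`, `confidence`, `success`,
#'   `AUxx_r` and `AUxx_c` columns and an `"episode_schedule"` attribute.
#' @export
#' @examples
#' fr <- simulate_au_frames(2, fps = 30, expressivity_level = 3,
#'                          episodes = c(happiness = 0.4), seed = 1)
#' nrow(fr)
simulate_au_frames <- function(duration_s, fps = 30, expressivity_level = 2,
                               episodes = NULL, activation_threshold = 1,
                               noise_sd = 0.2, failure_rate = 0, seed = NULL) {
  assert_scalar_number(duration_s, "duration_s", min = .Machine$double.eps)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    abort("`fps` must be a single positive number.", class = "dbm_bad_argument")
  }
  assert_scalar_number(expressivity_level, "expressivity_level", min = 0)
  n <- round(duration_s * fps)
  if (n < 1L) abort("duration shorter than one frame.", class = "dbm_bad_argument")
  map <- default_emotion_map()
  au_ids <- openface_au_ids()

  schedule <- rep("none", n)
  if (!is.null(episodes) && length(episodes)) {
    if (is.null(names(episodes)) || !all(names(episodes) %in% names(map))) {
      abort("`episodes` must be named by basic emotion.", class = "dbm_bad_argument")
    }
    if (any(episodes < 0) || sum(episodes) > 1 + 1e-12) {
      abort("episode fractions must be non-negative and sum to <= 1.",
            class = "dbm_bad_argument")
    }
    at <- 0L
    for (emo in names(episodes)) {
      len <- round(episodes[[emo]] * n)
      if (len > 0L) {
        idx <- seq.int(at + 1L, min(at + len, n))
        schedule[idx] <- emo
        at <- at + length(idx)
      }
    }
  }

  with_seed_if(seed, {
    base_sd <- 0.05 * expressivity_level
    intensity <- matrix(abs(rnorm(n * length(au_ids), 0, base_sd)),
                        nrow = n, dimnames = list(NULL, au_col(au_ids, "r")))
    if (expressivity_level == 0) intensity[] <- 0
    for (emo in unique(schedule[schedule != "none"])) {
      rows <- which(schedule == emo)
      cols <- au_col(map[[emo]], "r")
      intensity[rows, cols] <- expressivity_level +
        rnorm(length(rows) * length(cols), 0, noise_sd)
    }
    intensity <- clip(intensity, 0, 5)
    presence <- 1 * (intensity > activation_threshold)
    colnames(presence) <- au_col(au_ids, "c")
    success <- rep(1, n)
    if (failure_rate > 0) success[runif(n) < failure_rate] <- 0
    confidence <- clip(rnorm(n, 0.97, 0.015), 0, 1)
    confidence[success == 0] <- clip(rnorm(sum(success == 0), 0.3, 0.1), 0, 1)

    out <- tibble::as_tibble(cbind(
      data.frame(
        frame = seq_len(n),
        timestamp = (seq_len(n) - 1) / fps,
        confidence = confidence,
        success = success
      ),
      intensity, presence
    ))
    attr(out, "episode_schedule") <- schedule
    out
  })
}

#' Append a head-pose random walk to a frame table
#'
#' Translation follows a random walk whose per-frame step lengths are
#' log-normal with mean `movement_rate` and SD `0.5 * movement_rate`
#' (tracker units per frame) in a uniformly random direction; rotation
#' follows an independent small-angle component-wise Gaussian walk scaled so
#' the expected per-frame angular change norm equals `angle_rate` radians.
#' With zero rates the pose is exactly constant.  The realized step lengths
#' are stored in the `"step_lengths"` attribute for recovery checks.
#'
#' @param frames A frame table (e.g. from [simulate_au_frames()]).
#' @param movement_rate Expected per-frame translational step length (>= 0).
#' @param angle_rate Expected per-frame angular change norm in radians.
#' @param origin Length-3 starting translation (tracker units).
#' @param seed Optional integer seed.
#' @return `frames` with `pose_Tx/Ty/Tz` and `pose_Rx/Ry/Rz` columns added.
#' @export
simulate_pose <- function(frames, movement_rate = 0.5, angle_rate = 0.02,
                          origin = c(0, 0, 600), seed = NULL) {
  assert_scalar_number(movement_rate, "movement_rate", min = 0)
  assert_scalar_number(angle_rate, "angle_rate", min = 0)
  n <- nrow(frames)
  with_seed_if(seed, {
    if (movement_rate > 0) {
      sdlog <- sqrt(log(1 + 0.25))  # CV fixed at 0.5
      lens <- stats::rlnorm(n - 1L, log(movement_rate) - sdlog^2 / 2, sdlog)
      dirs <- matrix(rnorm(3L * (n - 1L)), ncol = 3L)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      steps <- dirs * lens
    } else {
      lens <- rep(0, n - 1L)
      steps <- matrix(0, n - 1L, 3L)
    }
    walk <- apply(steps, 2L, cumsum)
    if (is.null(dim(walk))) walk <- matrix(walk, nrow = 1L)
    trans <- rbind(origin, sweep(walk, 2L, origin, "+"))
    # E||N3(0, s^2 I)|| = s * sqrt(2) * gamma(2) / gamma(3/2)
    ang_sd <- angle_rate / (sqrt(2) * gamma(2) / gamma(1.5))
    rot_steps <- matrix(rnorm(3L * (n - 1L), 0, ang_sd), ncol = 3L)
    if (angle_rate == 0) rot_steps[] <- 0
    rot <- rbind(c(0, 0, 0), apply(rot_steps, 2L, cumsum))
    out <- dplyr::mutate(
      frames,
      pose_Tx = trans[, 1L], pose_Ty = trans[, 2L], pose_Tz = trans[, 3L],
      pose_Rx = rot[, 1L], pose_Ry = rot[, 2L], pose_Rz = rot[, 3L]
    )
    attr(out, "episode_schedule") <- attr(frames, "episode_schedule")
    attr(out, "step_lengths") <- lens
    out
  })
}

#' Simulate an amplitude trace with a known speech schedule
#'
#' Alternates high-amplitude speech bursts with near-silence in fixed cycles
#' (`cycle_s` seconds each, speech first), so the realized speech fraction
#' matches `voice_fraction` up to one burst granule (exactly, when the
#' duration is a whole number of cycles).  Speech is white noise at
#' `speech_amp` RMS; silence sits roughly 40 dB below it, far under the
#' detector's 25 dB dynamic threshold.
#'
#' @param voice_fraction Target speech fraction in `[0, 1]`.
#' @param duration_s Positive duration in seconds.
#' @param sample_rate Samples per second (default 8000).
#' @param cycle_s Burst cycle length in seconds (default 2.5).
#' @param speech_amp,silence_amp RMS amplitudes of the two regimes.
#' @param seed Optional integer seed.
#' @return An `amplitude_series` object: list with `samples`, `sample_rate`,
#'   `duration_s` and the ground-truth `speech_intervals` tibble.
#' @export
#' @examples
#' a <- simulate_audio(0.5, duration_s = 8, seed = 1)
#' a$speech_intervals
simulate_audio <- function(voice_fraction, duration_s, sample_rate = 8000,
                           cycle_s = 2.5, speech_amp = 0.3, silence_amp = 0.003,
                           seed = NULL) {
  if (!is_scalar_prob(voice_fraction)) {
    abort("`voice_fraction` must be a single value in [0, 1].",
          class = "dbm_bad_argument")
  }
  assert_scalar_number(duration_s, "duration_s", min = .Machine$double.eps)
  assert_scalar_number(sample_rate, "sample_rate", min = 1)
  n <- round(duration_s * sample_rate)

  starts <- seq(0, duration_s, by = cycle_s)
  ivs <- purrr::map_dfr(starts, function(s) {
    end <- min(s + voice_fraction * cycle_s, duration_s)
    if (end > s) tibble::tibble(start_s = s, end_s = end) else NULL
  })
  if (voice_fraction == 0) ivs <- tibble::tibble(start_s = numeric(), end_s = numeric())
  # merge touching intervals (voice_fraction = 1 collapses to one burst)
  if (nrow(ivs) > 1L) {
    merged <- ivs[1L, ]
    for (i in 2L:nrow(ivs)) {
      if (ivs$start_s[i] <= merged$end_s[nrow(merged)] + 1e-12) {
        merged$end_s[nrow(merged)] <- max(merged$end_s[nrow(merged)], ivs$end_s[i])
      } else {
        merged <- dplyr::bind_rows(merged, ivs[i, ])
      }
    }
    ivs <- merged
  }

  with_seed_if(seed, {
    x <- rnorm(n, 0, silence_amp)
    for (i in seq_len(nrow(ivs))) {
      idx <- seq.int(floor(ivs$start_s[i] * sample_rate) + 1L,
                     min(ceiling(ivs$end_s[i] * sample_rate), n))
      x[idx] <- rnorm(length(idx), 0, speech_amp)
    }
    structure(
      list(samples = x, sample_rate = sample_rate, duration_s = n / sample_rate,
           speech_intervals = ivs),
      class = "amplitude_series"
    )
  })
}

#' @export
print.amplitude_series <- function(x, ...) {
  cat(sprintf("<amplitude_series> %.2f s @ %d Hz, %d scheduled speech burst(s)\n",
              x$duration_s, as.integer(x$sample_rate), nrow(x$speech_intervals)))
  invisible(x)
}
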