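# Synthetic cohort generator: a latent depression severity (on the MADRS
# scale) drives both the clinician scores and the generative parameters of
# all 17 digital markers, so parameter recovery and longitudinal analysis
# can be tested end to end without clinical data.

#' Configuration of a simulated treatment cohort
#'
#' The defaults emulate the study conditions the pipeline targets: 18
#' responders assessed weekly over 4 weeks (days 0, 7, 14, 21, 28), clinic
#' MADRS at 3 visits (days 0, 14, 28), baseline MADRS from a truncated
#' normal with mean 34.1 and SD 4.9 on `[25, 45]`, a mean 60% MADRS
#' reduction by week 4 with a hard 30% responder floor, and an 18%
#' missing-completely-at-random assessment rate (which yields ~12 of 18
#' complete-case subjects in expectation).
#'
#' @param n_subjects Number of subjects (>= 2; default 18).
#' @param n_visits Number of clinic MADRS visits, evenly spaced over days
#'   0–28 (>= 2; default 3).
#' @param assessments_per_week Remote assessments per week (default 1,
#'   i.e. days 0, 7, 14, 21, 28).
#' @param fps Video frames per second (default 30).
#' @param response_fraction Mean proportional MADRS reduction at week 4
#'   (default 0.6); per-subject values are truncated-normal with SD
#'   `response_sd` and floor `min_response`.
#' @param response_sd Between-subject SD of the response fraction.
#' @param min_response Responder floor (default 0.30).
#' @param madrs_baseline_mean,madrs_baseline_sd,madrs_baseline_range
#'   Truncated-normal parameters of the baseline MADRS.
#' @param madrs_noise_sd Additive Gaussian noise on observed MADRS (points;
#'   default 2).  Scores are rounded to integers and clipped to `[0, 60]`
#'   unless the noise is exactly zero, in which case the latent values are
#'   returned unrounded so deterministic limits are exact.
#' @param missing_rate Probability that a scheduled remote assessment is
#'   absent (MCAR; default 0.18).
#' @param effect_sizes Optional named multipliers on the default
#'   severity-to-marker link slopes (names: `expressivity_level`,
#'   `voice_percentage`, `head_movement_mean`, `head_pose_change_mean`, or
#'   any `<emotion>_count`).
#' @param noise_sd `NULL` for defaults; a single number to scale every
#'   noise SD in the generator (0 gives the deterministic limit); or a
#'   named vector overriding individual marker noise SDs.
#' @param response_duration_s Seconds of video/audio per stimulus response
#'   (default 10, the protocol's minimum speech requirement).
#' @param sample_rate Audio sample rate in Hz (default 8000).
#' @param n_stimulus_images Size of the simulated stimulus pool.
#' @param seed Integer seed; [simulate_cohort()] refuses to run without one.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 18, n_visits = 3,
                          assessments_per_week = 1, fps = 30,
                          response_fraction = 0.6, response_sd = 0.08,
                          min_response = 0.30,
                          madrs_baseline_mean = 34.1, madrs_baseline_sd = 4.9,
                          madrs_baseline_range = c(25, 45),
                          madrs_noise_sd = 2, missing_rate = 0.18,
                          effect_sizes = NULL, noise_sd = NULL,
                          response_duration_s = 10, sample_rate = 8000,
                          n_stimulus_images = 900, seed = NULL) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_visits = as.integer(n_visits),
    assessments_per_week = assessments_per_week, fps = fps,
    response_fraction = response_fraction, response_sd = response_sd,
    min_response = min_response,
    madrs_baseline_mean = madrs_baseline_mean,
    madrs_baseline_sd = madrs_baseline_sd,
    madrs_baseline_range = madrs_baseline_range,
    madrs_noise_sd = madrs_noise_sd, missing_rate = missing_rate,
    effect_sizes = effect_sizes, noise_sd = noise_sd,
    response_duration_s = response_duration_s, sample_rate = sample_rate,
    n_stimulus_images = n_stimulus_images,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_subjects < 2L) {
    abort("`n_subjects` must be >= 2.", class = "dbm_bad_config")
  }
  if (cfg$n_visits < 2L) {
    abort("`n_visits` must be >= 2.", class = "dbm_bad_config")
  }
  for (p in c("response_fraction", "min_response", "missing_rate")) {
    if (!is_scalar_prob(cfg[[p]])) {
      abort(sprintf("`%s` must be a probability in [0, 1].", p),
            class = "dbm_bad_config")
    }
  }
  if (cfg$fps <= 0) abort("`fps` must be positive.", class = "dbm_bad_config")
  invisible(cfg)
}

# ---- latent severity -> marker link functions ------------------------------
# All links are linear in u = severity / 60 (the normalised MADRS deficit),
# clipped to each marker's valid range.  Transparent and invertible by
# design: the tests recover these parameters from generated data.

count_link_params <- function() {
  tibble::tibble(
    emotion = c("happiness", "sadness", "surprise", "fear", "anger", "disgust"),
    base    = c(0.16, 0.07, 0.05, 0.03, 0.03, 0.04),
    slope   = c(-0.10, 0.05, 0.00, 0.10, 0.12, 0.02)
  )
}

# Per-emotion episode-rate multipliers by stimulus class: positive images
# elicit more happiness, negative images more sadness/fear/anger/disgust.
class_modifiers <- function() {
  m <- rbind(
    happiness = c(neutral = 1.0, positive = 1.5, negative = 0.5),
    sadness   = c(1.0, 0.7, 1.4),
    surprise  = c(1.0, 1.2, 1.0),
    fear      = c(1.0, 0.8, 1.3),
    anger     = c(1.0, 0.8, 1.3),
    disgust   = c(1.0, 0.8, 1.3)
  )
  colnames(m) <- stimulus_classes()
  m
}

default_marker_noise <- function() {
  emo <- emotion_names()
  c(
    setNames(rep(0.02, 6), paste0(emo, "_count")),
    setNames(rep(0.06, 6), paste0(emo, "_intensity")),
    overall_expressivity = 0.12,
    voice_percentage = 0.04,
    head_movement_mean = 0.05,
    head_movement_sd = 0.03,
    head_pose_change_mean = 0.004
  )
}

marker_bounds <- function() {
  emo <- emotion_names()
  lo <- c(setNames(rep(0, 12), c(paste0(emo, "_count"), paste0(emo, "_intensity"))),
          overall_expressivity = 0, voice_percentage = 0,
          head_movement_mean = 0, head_movement_sd = 0,
          head_pose_change_mean = 0)
  hi <- c(setNames(rep(1, 6), paste0(emo, "_count")),
          setNames(rep(5, 6), paste0(emo, "_intensity")),
          overall_expressivity = 30, voice_percentage = 1,
          head_movement_mean = Inf, head_movement_sd = Inf,
          head_pose_change_mean = Inf)
  list(lo = lo, hi = hi)
}

effect_multiplier <- function(effect_sizes, name) {
  if (is.null(effect_sizes) || is.null(effect_sizes[[name]])) 1 else effect_sizes[[name]]
}

#' Latent state implied by a severity value
#'
#' Deterministic link functions from a MADRS-scale severity to the
#' generative parameters: mean active-AU intensity (`expressivity_level`,
#' 0–5), speech fraction (`voice_fraction`), translational step rate
#' (`movement_rate`, tracker units/frame), angular step rate
#' (`angle_rate`, rad/frame), and per-emotion episode fractions.  All are
#' linear in `severity / 60` and clipped to valid ranges; lower severity
#' means more expressivity, speech and movement.
#'
#' @param severity Numeric severity value(s) in `[0, 60]`.
#' @param effect_sizes Optional named slope multipliers (see
#'   [cohort_config()]).
#' @return Tibble with one row per severity value.
#' @export
latent_state <- function(severity, effect_sizes = NULL) {
  if (any(severity < 0 | severity > 60)) {
    abort("severity must lie in [0, 60] (the MADRS range).",
          class = "dbm_bad_argument")
  }
  u <- severity / 60
  cl <- count_link_params()
  fracs <- sapply(seq_len(nrow(cl)), function(i) {
    es <- effect_multiplier(effect_sizes, paste0(cl$emotion[i], "_count"))
    clip(cl$base[i] + es * cl$slope[i] * u, 0, 0.25)
  })
  if (is.null(dim(fracs))) fracs <- matrix(fracs, nrow = 1)
  colnames(fracs) <- paste0("frac_", cl$emotion)
  tibble::tibble(
    severity = severity,
    expressivity_level = clip(
      3.5 - effect_multiplier(effect_sizes, "expressivity_level") * 3.5 * u, 0, 5),
    voice_fraction = clip(
      0.88 - effect_multiplier(effect_sizes, "voice_percentage") * 0.55 * u,
      0.02, 0.95),
    movement_rate = clip(
      0.85 - effect_multiplier(effect_sizes, "head_movement_mean") * 0.60 * u,
      0.01, 5),
    angle_rate = clip(
      0.05 - effect_multiplier(effect_sizes, "head_pose_change_mean") * 0.035 * u,
      0.001, 1)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(fracs))
}

# Fraction of emotion m's prototype AUs shared with emotion e's; the
# diagonal is 1.  Episodes of e raise m's mean constituent intensity in
# proportion to this overlap, both in rendered frames and in the
# marker-level links below, so the two simulation levels agree.
au_overlap_matrix <- function(map = default_emotion_map()) {
  emo <- names(map)
  o <- matrix(0, length(emo), length(emo), dimnames = list(emo, emo))
  for (m in emo) for (e in emo) {
    o[m, e] <- length(intersect(map[[m]], map[[e]])) / length(map[[m]])
  }
  o
}

# Noise-free marker values implied by a latent state, for one stimulus
# class.  Returns a tibble with one column per marker in marker_catalog().
# Emotion intensity: constituent-AU mean = expressivity during the
# emotion's own episodes, overlap-weighted expressivity during other
# episodes, and the idle-baseline level (mean |N(0, 0.05 E)| ~ 0.04 E)
# elsewhere.
true_markers <- function(state, class) {
  mods <- class_modifiers()[, class]
  emo <- emotion_names()
  ov <- au_overlap_matrix()
  fracs <- sapply(emo, function(e) clip(state[[paste0("frac_", e)]] * mods[[e]], 0, 0.3))
  if (is.null(dim(fracs))) fracs <- matrix(fracs, nrow = 1, dimnames = list(NULL, emo))
  f_total <- rowSums(fracs)
  out <- tibble::tibble(.rows = nrow(state))
  for (e in emo) {
    out[[paste0(e, "_count")]] <- fracs[, e]
    out[[paste0(e, "_intensity")]] <- state$expressivity_level *
      (as.vector(fracs %*% ov[e, ]) + 0.04 * (1 - f_total))
  }
  out$overall_expressivity <-
    rowSums(out[paste0(emo, "_intensity")])
  out$voice_percentage <- state$voice_fraction
  out$head_movement_mean <- state$movement_rate
  out$head_movement_sd <- 0.5 * state$movement_rate
  out$head_pose_change_mean <- state$angle_rate
  out[marker_catalog()]
}

resolve_noise <- function(cfg) {
  sds <- default_marker_noise()
  madrs_sd <- cfg$madrs_noise_sd
  resp_sd <- cfg$response_sd
  ns <- cfg$noise_sd
  if (!is.null(ns)) {
    if (is.numeric(ns) && length(ns) == 1L && is.null(names(ns))) {
      sds <- sds * ns
      madrs_sd <- madrs_sd * ns
      resp_sd <- resp_sd * ns
    } else if (is.numeric(ns) && !is.null(names(ns))) {
      bad <- setdiff(names(ns), names(sds))
      if (length(bad)) {
        abort(sprintf("unknown marker(s) in noise_sd: %s",
                      paste(bad, collapse = ", ")),
              class = "dbm_bad_config")
      }
      sds[names(ns)] <- ns
    } else {
      abort("`noise_sd` must be a scalar or a named numeric vector.",
            class = "dbm_bad_config")
    }
  }
  list(marker = sds, madrs = madrs_sd, response = resp_sd)
}

#' Simulate a longitudinal treatment cohort
#'
#' Generates a full synthetic study: per-subject baseline MADRS and response
#' trajectories, clinic MADRS scores, per-assessment latent states, and the
#' tidy 17-marker table (`subject_id, study_day, stimulus_class, marker,
#' value`).  With `render = TRUE` it additionally builds the stimulus
#' manifest and renders every observed assessment down to OpenFace-dialect
#' frame tables and amplitude traces, the raw inputs of
#' [extract_markers()].
#'
#' Identical seeds give bit-identical output.  The latent severity declines
#' linearly from baseline to `baseline * (1 - response)` at day 28; all
#' markers are generated monotonically in severity through the
#' [latent_state()] links.
#'
#' @param config A [cohort_config()]; its `seed` must be set.
#' @param render Also render frame tables and audio per assessment
#'   (slower; default `FALSE`).
#' @return A `cohort` object: list with `config`, `subjects`, `madrs`,
#'   `schedule`, `latent`, `markers`, and (when rendered) `pool`,
#'   `manifest`, `assessments`.
#' @export
#' @examples
#' ch <- simulate_cohort(cohort_config(n_subjects = 4, seed = 1))
#' head(ch$markers)
simulate_cohort <- function(config = cohort_config(), render = FALSE) {
  validate_cohort_config(config)
  if (is.null(config$seed)) {
    abort("`config$seed` is missing: refusing to generate a non-reproducible cohort.",
          class = "dbm_missing_seed")
  }
  noise <- resolve_noise(config)

  withr::with_seed(config$seed, {
    n <- config$n_subjects
    subjects <- tibble::tibble(
      subject_id = sprintf("S%02d", seq_len(n)),
      baseline_madrs = round(rtrunc_norm(
        n, config$madrs_baseline_mean, config$madrs_baseline_sd,
        config$madrs_baseline_range[1], config$madrs_baseline_range[2])),
      response = rtrunc_norm(n, config$response_fraction, noise$response,
                             config$min_response, 0.9)
    )

    severity_at <- function(subject, day) {
      i <- match(subject, subjects$subject_id)
      clip(subjects$baseline_madrs[i] *
             (1 - subjects$response[i] * day / 28), 0, 60)
    }

    madrs_days <- unique(round(seq(0, 28, length.out = config$n_visits)))
    madrs <- tidyr::expand_grid(subject_id = subjects$subject_id,
                                study_day = madrs_days) |>
      dplyr::mutate(
        visit = assign_bin(.data$study_day),
        latent = severity_at(.data$subject_id, .data$study_day),
        madrs = .data$latent + rnorm(dplyr::n(), 0, noise$madrs)
      )
    if (noise$madrs > 0) {
      madrs$madrs <- clip(round(madrs$madrs), 0, 60)
    }
    madrs <- dplyr::select(madrs, "subject_id", "visit", "study_day", "madrs")

    assess_days <- seq(0, 28, by = 7 / config$assessments_per_week)
    schedule <- tidyr::expand_grid(subject_id = subjects$subject_id,
                                   study_day = assess_days) |>
      dplyr::mutate(observed = runif(dplyr::n()) >= config$missing_rate)

    observed <- dplyr::filter(schedule, .data$observed)
    latent <- dplyr::bind_cols(
      observed["subject_id"], observed["study_day"],
      latent_state(severity_at(observed$subject_id, observed$study_day),
                   config$effect_sizes)
    )

    markers <- purrr::map_dfr(stimulus_classes(), function(cl) {
      tm <- true_markers(latent, cl)
      long <- tidyr::pivot_longer(
        dplyr::bind_cols(latent[c("subject_id", "study_day")], tm),
        -c("subject_id", "study_day"),
        names_to = "marker", values_to = "truth"
      )
      long$stimulus_class <- cl
      long
    })
    b <- marker_bounds()
    markers <- markers |>
      dplyr::mutate(
        value = clip(
          .data$truth + rnorm(dplyr::n(), 0, noise$marker[.data$marker]),
          b$lo[.data$marker], b$hi[.data$marker])
      ) |>
      dplyr::select("subject_id", "study_day", "stimulus_class",
                    "marker", "value", "truth") |>
      dplyr::arrange(.data$subject_id, .data$study_day,
                     .data$stimulus_class, .data$marker)

    out <- structure(
      list(config = config, subjects = subjects, madrs = madrs,
           schedule = schedule, latent = latent, markers = markers),
      class = "cohort"
    )
    if (render) out <- render_cohort(out, noise)
    out
  })
}

# Render frame tables and audio for every observed assessment.  Runs inside
# the cohort RNG stream, so rendering is part of the same deterministic draw.
render_cohort <- function(cohort, noise) {
  cfg <- cohort$config
  pool <- simulate_stimulus_pool(cfg$n_stimulus_images)
  obs <- dplyr::filter(cohort$schedule, .data$observed)
  days <- sort(unique(obs$study_day))
  manifest <- simulate_study_sequences(pool, cohort$subjects$subject_id, days)
  manifest <- dplyr::semi_join(manifest, obs, by = c("subject_id", "study_day"))

  lat <- cohort$latent
  mods <- class_modifiers()
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    mrow <- manifest[i, ]
    st <- lat[lat$subject_id == mrow$subject_id &
                lat$study_day == mrow$study_day, ]
    fracs <- sapply(emotion_names(), function(e) {
      clip(st[[paste0("frac_", e)]] * mods[e, mrow$valence_class], 0, 0.3)
    })
    frames <- simulate_au_frames(
      cfg$response_duration_s, cfg$fps,
      expressivity_level = st$expressivity_level,
      episodes = fracs
    )
    frames <- simulate_pose(frames, movement_rate = st$movement_rate,
                            angle_rate = st$angle_rate)
    audio <- simulate_audio(
      clip(st$voice_fraction + rnorm(1, 0, noise$marker[["voice_percentage"]]),
           0.02, 0.95),
      cfg$response_duration_s, cfg$sample_rate
    )
    rows[[i]] <- tibble::tibble(
      subject_id = mrow$subject_id, study_day = mrow$study_day,
      position = mrow$position, image_id = mrow$image_id,
      valence_class = mrow$valence_class,
      sample_rate = cfg$sample_rate,
      frames = list(frames), audio = list(audio)
    )
  }
  cohort$pool <- pool
  cohort$manifest <- manifest
  cohort$assessments <- dplyr::bind_rows(rows)
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  obs <- sum(x$schedule$observed)
  cat(sprintf(
    "<cohort> %d subjects, %d scheduled assessments (%d observed), %d MADRS visits%s\n",
    x$config$n_subjects, nrow(x$schedule), obs,
    length(unique(x$madrs$study_day)),
    if (!is.null(x$assessments)) sprintf(", %d rendered responses", nrow(x$assessments)) else ""
  ))
  invisible(x)
}
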