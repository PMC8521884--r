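# Cohort generator: reproducibility, MADRS structure, deterministic limits,
# latent coupling, and the frame/audio/pose signal generators.

test_that("cohort generation is reproducible and seed-sensitive", {
  a <- simulate_cohort(cohort_config(n_subjects = 6, seed = 3))
  b <- simulate_cohort(cohort_config(n_subjects = 6, seed = 3))
  expect_identical(a$markers, b$markers)
  expect_identical(a$madrs, b$madrs)
  c <- simulate_cohort(cohort_config(n_subjects = 6, seed = 4))
  expect_false(isTRUE(all.equal(mean(a$markers$value), mean(c$markers$value))))
  expect_error(simulate_cohort(cohort_config(n_subjects = 6)),
               class = "dbm_missing_seed")
  expect_error(cohort_config(n_subjects = 1, seed = 1), class = "dbm_bad_config")
  expect_error(cohort_config(missing_rate = 1.2, seed = 1),
               class = "dbm_bad_config")
})

test_that("MADRS table has the study structure: 18 x 3, baselines in [25,45]", {
  ch <- simulate_cohort(cohort_config(n_subjects = 18, n_visits = 3, seed = 7))
  expect_equal(nrow(ch$madrs), 18L * 3L)
  base <- ch$madrs$madrs[ch$madrs$study_day == 0]
  expect_true(all(base >= 25 - 2 * 3 & base <= 45 + 2 * 3))  # noise on top of range
  expect_true(all(ch$subjects$baseline_madrs >= 25 &
                    ch$subjects$baseline_madrs <= 45))
  expect_setequal(unique(ch$madrs$visit), c("baseline", "week2", "week4"))
})

test_that("no missingness means a full schedule; missing rate thins it", {
  full <- simulate_cohort(cohort_config(n_subjects = 8, missing_rate = 0, seed = 2))
  expect_true(all(full$schedule$observed))
  expect_equal(nrow(dplyr::filter(full$schedule, .data$observed)), 8L * 5L)
  some <- simulate_cohort(cohort_config(n_subjects = 18, missing_rate = 0.4, seed = 2))
  expect_lt(sum(some$schedule$observed), nrow(some$schedule))
})

test_that("deterministic limit: week4/baseline MADRS ratio equals 1 - response", {
  ch <- simulate_cohort(cohort_config(n_subjects = 10, response_fraction = 0.30,
                                      noise_sd = 0, seed = 5))
  wide <- tidyr::pivot_wider(ch$madrs[c("subject_id", "visit", "madrs")],
                             names_from = "visit", values_from = "madrs")
  expect_equal(wide$week4 / wide$baseline, rep(0.70, 10), tolerance = 1e-9)
  # and all subjects clear the responder floor
  expect_true(all(responder_filter(wide$baseline, wide$week4)))
})

test_that("latent severity couples negatively and monotonically to markers", {
  ch <- simulate_cohort(cohort_config(n_subjects = 18, noise_sd = 1e-6, seed = 8))
  sp <- cor(ch$latent$severity, ch$latent$expressivity_level, method = "spearman")
  expect_lte(sp, -0.8)
  for (col in c("voice_fraction", "movement_rate", "angle_rate")) {
    expect_lte(cor(ch$latent$severity, ch$latent[[col]], method = "spearman"), -0.8)
  }
  # marker-level values inherit the coupling
  oe <- dplyr::filter(ch$markers, .data$marker == "overall_expressivity",
                      .data$stimulus_class == "neutral")
  sev <- ch$latent$severity[match(paste(oe$subject_id, oe$study_day),
                                  paste(ch$latent$subject_id, ch$latent$study_day))]
  expect_lte(cor(sev, oe$value, method = "spearman"), -0.8)
})

test_that("AU frame generator honours row count, ranges and null expressivity", {
  fr <- simulate_au_frames(10, fps = 30, expressivity_level = 2,
                           episodes = c(happiness = 0.3), seed = 1)
  expect_equal(nrow(fr), 300L)
  rcols <- grep("_r$", names(fr), value = TRUE)
  ccols <- grep("_c$", names(fr), value = TRUE)
  expect_true(all(as.matrix(fr[rcols]) >= 0 & as.matrix(fr[rcols]) <= 5))
  expect_true(all(as.matrix(fr[ccols]) %in% c(0, 1)))
  # presence iff intensity above the activation threshold
  expect_equal(as.vector(as.matrix(fr[ccols])),
               as.vector(1 * (as.matrix(fr[rcols]) > 1)))
  blank <- simulate_au_frames(2, fps = 30, expressivity_level = 0, seed = 1)
  expect_true(all(as.matrix(blank[rcols]) == 0))
  expect_true(all(as.matrix(blank[ccols]) == 0))
  expect_error(simulate_au_frames(10, fps = 0), class = "dbm_bad_argument")
  expect_error(simulate_au_frames(-1), class = "dbm_bad_argument")
})

test_that("injected episode schedule is recovered by downstream labelling", {
  fr <- simulate_au_frames(10, fps = 30, expressivity_level = 3,
                           episodes = c(happiness = 0.4), seed = 6)
  sched <- attr(fr, "episode_schedule")
  expect_equal(mean(sched == "happiness"), 0.4, tolerance = 1 / 300)
  expect_equal(emotion_count(fr, "happiness"), mean(sched == "happiness"),
               tolerance = 1e-12)
})

test_that("audio generator hits the scheduled voice fraction", {
  a <- simulate_audio(0.5, duration_s = 20, seed = 3)
  sched <- sum(a$speech_intervals$end_s - a$speech_intervals$start_s) / a$duration_s
  expect_equal(sched, 0.5, tolerance = 0.01)
  expect_equal(length(a$samples), 20 * 8000)
  a0 <- simulate_audio(0, duration_s = 5, seed = 3)
  expect_equal(nrow(a0$speech_intervals), 0L)
  expect_true(all(abs(a0$samples) < 0.05))
  a1 <- simulate_audio(1, duration_s = 5, seed = 3)
  expect_equal(nrow(a1$speech_intervals), 1L)
  expect_equal(a1$speech_intervals$end_s - a1$speech_intervals$start_s, 5)
  expect_error(simulate_audio(0.5, -1), class = "dbm_bad_argument")
  expect_error(simulate_audio(1.5, 1), class = "dbm_bad_argument")
})

test_that("pose walk: zero rate is constant, realized steps are recoverable", {
  fr <- simulate_au_frames(2, fps = 30, seed = 1)
  still <- simulate_pose(fr, movement_rate = 0, angle_rate = 0, seed = 2)
  expect_equal(var(still$pose_Tx), 0)
  expect_equal(head_pose_change(still), 0)
  expect_equal(mean(framewise_displacement(still)$displacement), 0)

  moving <- simulate_pose(simulate_au_frames(30, fps = 30, seed = 1),
                          movement_rate = 0.5, angle_rate = 0.02, seed = 4)
  d <- framewise_displacement(moving)$displacement
  expect_equal(d, attr(moving, "step_lengths"), tolerance = 1e-12)
  expect_equal(mean(d), 0.5, tolerance = 0.05)  # 900 frames
})

test_that("marker-level truths agree with rendered extraction (consistency)", {
  ch <- simulate_cohort(cohort_config(n_subjects = 2, missing_rate = 0,
                                      response_duration_s = 6, seed = 11),
                        render = TRUE)
  mk <- extract_markers(ch$assessments)
  cmp <- dplyr::inner_join(
    mk, ch$markers,
    by = c("subject_id", "study_day", "stimulus_class", "marker"),
    suffix = c("_ex", "_sim"))
  agg <- cmp |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(ex = mean(.data$value_ex), tr = mean(.data$truth))
  # same scale (within 15% or 0.05 absolute) and same ordering across markers
  expect_true(all(abs(agg$ex - agg$tr) <= pmax(0.15 * abs(agg$tr), 0.05)))
  expect_gt(cor(agg$ex, agg$tr, method = "spearman"), 0.95)
})
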