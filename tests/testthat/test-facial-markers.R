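# Facial markers: quality gate, per-frame labelling, counts, intensities,
# expressivity, and their algebraic invariants.

test_that("quality gate retains exactly the flagged frames", {
  fr <- frames_with_aus(rep(list(integer()), 300))
  expect_identical(nrow(filter_valid_frames(fr)), 300L)
  fr$success[1:25] <- 0
  fr$confidence[26:40] <- 0.5
  kept <- filter_valid_frames(fr)
  expect_equal(nrow(kept), 260L)
  expect_equal(attr(kept, "n_total"), 300L)
  expect_equal(attr(kept, "n_retained"), 260L)
  # all frames bad -> markers missing, not zero
  fr$success[] <- 0
  expect_true(all(is.na(facial_markers(fr)$value)))
  expect_true(all(is.na(movement_markers(frames_with_pose(matrix(0, 3, 3)) |>
                                           dplyr::mutate(success = 0))$value)))
})

test_that("frame labelling follows the AU prototype map", {
  # blank face -> none
  expect_equal(frame_emotion_label(frames_with_aus(list(integer()))), "none")
  # AU6+12 -> happiness with unique full match
  expect_equal(frame_emotion_label(frames_with_aus(list(c(6L, 12L)))), "happiness")
  # AU1,2,5,26 -> surprise (4/4) beats fear (4/7)
  expect_equal(frame_emotion_label(frames_with_aus(list(c(1L, 2L, 5L, 26L)))),
               "surprise")
  # full fear prototype -> fear, despite surprise also matching 4/4
  expect_equal(frame_emotion_label(frames_with_aus(list(c(1L, 2L, 4L, 5L, 7L, 20L, 26L)))),
               "fear")
  # AU15 alone reaches disgust's 0.5 match floor (1 of its 2 AUs)
  expect_equal(frame_emotion_label(frames_with_aus(list(15L))), "disgust")
  # below the 0.5 match floor everywhere -> none (AU1 alone)
  expect_equal(frame_emotion_label(frames_with_aus(list(1L))), "none")
})

test_that("counts are labelled-frame fractions and partition to one", {
  active <- c(rep(list(c(6L, 12L)), 40), rep(list(c(1L, 4L, 15L)), 25),
              rep(list(integer()), 35))
  fr <- frames_with_aus(active)
  expect_equal(emotion_count(fr, "happiness"), 0.40)
  expect_equal(emotion_count(fr, "sadness"), 0.25)
  labels <- frame_emotion_label(fr)
  counts <- vapply(names(default_emotion_map()),
                   function(e) emotion_count(fr, e), numeric(1))
  expect_equal(sum(counts) + mean(labels == "none"), 1, tolerance = 1e-12)
})

test_that("intensity markers equal brute-force per-frame mean-of-means", {
  withr::with_seed(21, {
    fr <- simulate_au_frames(4, fps = 30, expressivity_level = 2.5,
                             episodes = c(happiness = 0.3, anger = 0.2,
                                          disgust = 0.1))
    map <- default_emotion_map()
    for (e in names(map)) {
      # independent loop oracle
      vals <- vapply(seq_len(nrow(fr)), function(i) {
        mean(vapply(map[[e]], function(au) fr[[sprintf("AU%02d_r", au)]][i],
                    numeric(1)))
      }, numeric(1))
      expect_equal(emotion_intensity(fr, e), mean(vals), tolerance = 1e-12)
    }
  })
})

test_that("constant single-emotion signal gives its intensity back", {
  fr <- frames_with_aus(rep(list(c(6L, 12L)), 50), level = 3)
  expect_equal(emotion_intensity(fr, "happiness"), 3)
  expect_equal(emotion_count(fr, "happiness"), 1)
  blank <- frames_with_aus(rep(list(integer()), 10))
  expect_equal(overall_expressivity(blank), 0)
  expect_true(all(facial_markers(blank)$value == 0))
})

test_that("overall expressivity is the sum of the six emotion intensities", {
  withr::with_seed(22, {
    fr <- simulate_au_frames(4, fps = 30, expressivity_level = 3,
                             episodes = c(fear = 0.2, sadness = 0.3))
    parts <- vapply(names(default_emotion_map()),
                    function(e) emotion_intensity(fr, e), numeric(1))
    expect_equal(overall_expressivity(fr), sum(parts), tolerance = 1e-12)
    # the alternative raw-AU composite is also finite and nonnegative
    expect_gte(overall_expressivity(fr, from = "aus"), 0)
  })
})

test_that("intensity markers scale linearly; counts fixed under scaling", {
  withr::with_seed(23, {
    fr <- simulate_au_frames(3, fps = 30, expressivity_level = 3,
                             episodes = c(happiness = 0.4, anger = 0.3))
    for (cc in c(0.5, 0.2)) {
      scaled <- fr
      rcols <- grep("_r$", names(fr), value = TRUE)
      scaled[rcols] <- fr[rcols] * cc
      for (e in c("happiness", "anger")) {
        expect_equal(emotion_intensity(scaled, e), cc * emotion_intensity(fr, e),
                     tolerance = 1e-12)
      }
      expect_equal(overall_expressivity(scaled), cc * overall_expressivity(fr),
                   tolerance = 1e-12)
      # presence flags untouched -> counts unchanged
      expect_equal(emotion_count(scaled, "happiness"),
                   emotion_count(fr, "happiness"))
    }
  })
})

test_that("markers are order-invariant and concatenation-consistent", {
  withr::with_seed(24, {
    fr1 <- simulate_au_frames(2, fps = 30, expressivity_level = 2,
                              episodes = c(sadness = 0.5))
    fr2 <- simulate_au_frames(3, fps = 30, expressivity_level = 3,
                              episodes = c(happiness = 0.4))
    perm <- fr1[sample(nrow(fr1)), ]
    m1 <- facial_markers(fr1)
    expect_equal(facial_markers(perm)$value, m1$value, tolerance = 1e-12)
    fr2$frame <- fr2$frame + nrow(fr1)
    combo <- facial_markers(dplyr::bind_rows(fr1, fr2))
    m2 <- facial_markers(fr2)
    w <- c(nrow(fr1), nrow(fr2)) / (nrow(fr1) + nrow(fr2))
    expect_equal(combo$value, w[1] * m1$value + w[2] * m2$value,
                 tolerance = 1e-12)
  })
})
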