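# Valence normalisation, classification, sequence assembly, validity rule.

test_that("z-scoring uses the population SD and centres exactly", {
  expect_equal(zscore_valences(c(1, 2, 3)),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  withr::with_seed(11, {
    raw <- runif(900, 1, 7)
    z <- zscore_valences(raw)
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-12)
  })
  expect_error(zscore_valences(rep(2, 5)), class = "dbm_zero_variance")
  expect_error(zscore_valences(1), class = "dbm_bad_argument")
})

test_that("valence classes partition the line with buffer zones", {
  expect_equal(classify_valence(0), "neutral")
  expect_equal(classify_valence(c(-0.5, 0.5)), c("neutral", "neutral"))
  expect_equal(classify_valence(c(1.5, 1.6)), c("positive", "positive"))
  expect_equal(classify_valence(c(-1.5, -2)), c("negative", "negative"))
  expect_equal(classify_valence(c(1.0, -1.0, 0.51, 1.49)),
               rep("buffer", 4))
  expect_error(classify_valence(Inf), class = "dbm_bad_argument")
  expect_error(classify_valence(NA_real_), class = "dbm_bad_argument")
  # totality: every finite z gets exactly one class
  z <- seq(-4, 4, by = 0.01)
  expect_true(all(classify_valence(z) %in%
                    c("negative", "neutral", "positive", "buffer")))
})

test_that("sequences have the fixed 7/3/3 composition and neutral padding", {
  pool <- simulate_stimulus_pool(900, seed = 4)
  s <- build_sequence(pool, seed = 5)
  expect_equal(nrow(s), 13L)
  expect_equal(sum(s$valence_class == "neutral"), 7L)
  expect_equal(sum(s$valence_class == "positive"), 3L)
  expect_equal(sum(s$valence_class == "negative"), 3L)
  expect_equal(s$valence_class[c(1, 13)], c("neutral", "neutral"))
  adj <- cbind(s$valence_class[-13], s$valence_class[-1])
  expect_false(any(adj[, 1] %in% c("positive", "negative") &
                     adj[, 2] %in% c("positive", "negative")))
  # classes agree with the pool
  expect_equal(s$valence_class,
               pool$valence_class[match(s$image_id, pool$image_id)])
})

test_that("no-repeat constraint holds across calls and a 5-visit study", {
  pool <- simulate_stimulus_pool(900, seed = 4)
  s1 <- build_sequence(pool, seed = 1)
  s2 <- build_sequence(pool, history = s1$image_id, seed = 2)
  expect_length(intersect(s1$image_id, s2$image_id), 0L)

  manifest <- simulate_study_sequences(pool, c("a", "b", "c"),
                                       c(0, 7, 14, 21, 28), seed = 9)
  per_subject <- split(manifest$image_id, manifest$subject_id)
  for (ids in per_subject) expect_false(anyDuplicated(ids) > 0)
})

test_that("pool exhaustion raises a classed error naming the depleted class", {
  pool <- simulate_stimulus_pool(900, seed = 4)
  tight <- dplyr::bind_rows(
    head(pool[pool$valence_class == "neutral", ], 7),
    head(pool[pool$valence_class == "positive", ], 3),
    head(pool[pool$valence_class == "negative", ], 3)
  )
  s1 <- build_sequence(tight, seed = 1)
  expect_equal(nrow(s1), 13L)
  err <- expect_error(build_sequence(tight, history = s1$image_id, seed = 2),
                      class = "dbm_pool_exhausted")
  expect_true(err$depleted_class %in% c("neutral", "positive", "negative"))
  expect_match(conditionMessage(err), err$depleted_class)
})

test_that("sequence invariants hold over random pools (property)", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      pool <- prepare_stimulus_pool(tibble::tibble(
        image_id = sprintf("i%03d", 1:300),
        raw_valence = rnorm(300, 4, runif(1, 0.8, 2))
      ))
      s <- build_sequence(pool)
      expect_equal(table(s$valence_class)[c("neutral", "positive", "negative")],
                   table(factor(c(rep("neutral", 7), rep("positive", 3),
                                  rep("negative", 3))))[c("neutral", "positive", "negative")])
      expect_false(anyDuplicated(s$image_id) > 0)
    }
  })
})

test_that("minimum-speech rule passes at exactly 10 s", {
  expect_true(validate_response(10))
  expect_false(validate_response(9.99))
  expect_false(validate_response(0))
  expect_equal(validate_response(c(12, 3)), c(TRUE, FALSE))
  expect_error(validate_response(-1), class = "dbm_bad_argument")
})
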