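# Visit binning, complete-case aggregation, RM-ANOVA and friends, and the
# MADRS clinical rules.

test_that("study days map to the printed visit windows", {
  expect_equal(assign_bin(c(0, 6)), c("baseline", "baseline"))
  expect_equal(assign_bin(c(7, 14, 21)), rep("week2", 3))
  expect_equal(assign_bin(c(22, 28, 35)), rep("week4", 3))
  expect_equal(assign_bin(36), "excluded")
  expect_error(assign_bin(-1), class = "dbm_bad_argument")
})

test_that("aggregation averages within bins and drops incomplete subjects", {
  d <- tibble::tibble(
    subject_id = c(rep("a", 4), rep("b", 2), rep("c", 3)),
    study_day = c(0, 7, 14, 28, 7, 14, 0, 21, 22),
    value = c(1, 0.2, 0.4, 2, 5, 5, 3, 4, 5)
  )
  vm <- visit_matrix(d)
  # b has no baseline or week4 -> dropped
  expect_setequal(vm$subject_id, c("a", "c"))
  expect_equal(attr(vm, "dropped"), "b")
  expect_equal(vm$week2[vm$subject_id == "a"], 0.3)  # mean of 0.2, 0.4
  expect_equal(attr(vm, "n_complete"), 2L)
  expect_equal(attr(vm, "n_total"), 3L)
  # fewer than 2 complete subjects -> refused with diagnostic
  expect_error(visit_matrix(d[d$subject_id != "c", ]),
               class = "dbm_insufficient_n")
})

test_that("complete-case n matches the missingness mask of a known cohort", {
  ch <- simulate_cohort(cohort_config(n_subjects = 18, seed = 13))
  mask <- ch$schedule |>
    dplyr::filter(.data$observed) |>
    dplyr::mutate(bin = assign_bin(.data$study_day)) |>
    dplyr::distinct(.data$subject_id, .data$bin) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n == 3L)
  d <- dplyr::filter(ch$markers, .data$marker == "voice_percentage",
                     .data$stimulus_class == "neutral")
  vm <- visit_matrix(d)
  expect_equal(sort(vm$subject_id), sort(mask$subject_id))
})

test_that("min-max normalisation is exact and refused for constants", {
  vm <- structure(tibble::tibble(subject_id = c("a", "b", "c"),
                                 baseline = c(2, 2, 2), week2 = c(4, 4, 4),
                                 week4 = c(6, 6, 6)),
                  class = c("visit_matrix", "tbl_df", "tbl", "data.frame"))
  nm <- minmax_normalize(vm)
  expect_equal(unique(nm$baseline), 0)
  expect_equal(unique(nm$week2), 0.5)
  expect_equal(unique(nm$week4), 1)
  flat <- vm
  flat$week2 <- 2; flat$week4 <- 2
  expect_error(minmax_normalize(flat), class = "dbm_zero_variance")
})

test_that("rm_anova reports the analytic df and handles degenerate input", {
  withr::with_seed(41, {
    m <- matrix(rnorm(54), 18, 3)
    fit <- rm_anova(m)
    expect_equal(fit$df_num, 2L)
    expect_equal(fit$df_den, 34L)
    # identical columns -> no time effect at all
    same <- matrix(rnorm(18), 18, 3)[, c(1, 1, 1)]
    fit0 <- rm_anova(same)
    expect_equal(fit0$statistic, 0)
    expect_equal(fit0$p.value, 1)
    # perfectly additive data -> zero error variance, infinite F
    add <- outer(rnorm(10), c(0, 1, 2), "+")
    expect_warning(fitI <- rm_anova(add), "degenerate")
    expect_identical(fitI$statistic, Inf)
    expect_identical(fitI$p.value, 0)
  })
  expect_error(rm_anova(matrix(1, 1, 3)), class = "dbm_insufficient_n")
})

test_that("rm_anova matches both the loop oracle and aov on random data", {
  withr::with_seed(42, {
    for (i in 1:25) {
      m <- random_rm_matrix()
      fit <- rm_anova(m)
      ora <- oracle_rm_anova(m)
      expect_equal(fit$statistic, ora$F, tolerance = 1e-10)
      expect_equal(fit$p.value, ora$p, tolerance = 1e-10)
    }
    # independent library route once
    m <- random_rm_matrix(10, 3)
    long <- data.frame(y = as.vector(m), s = factor(rep(1:10, 3)),
                       t = factor(rep(1:3, each = 10)))
    a <- summary(stats::aov(y ~ t + Error(s / t), long))
    f_ref <- a[["Error: s:t"]][[1]]["t", "F value"]
    expect_equal(rm_anova(m)$statistic, f_ref, tolerance = 1e-8)
  })
})

test_that("Mauchly's W matches the mlm reference and k = 2 is skipped", {
  withr::with_seed(43, {
    for (i in 1:25) {
      m <- random_rm_matrix(sample(7:15, 1), sample(3:5, 1))
      mine <- mauchly_test(m)
      ref <- oracle_mauchly(m)
      expect_equal(mine$W, ref$W, tolerance = 1e-10)
      expect_equal(mine$p.value, ref$p, tolerance = 1e-10)
    }
  })
  two <- mauchly_test(matrix(rnorm(20), 10, 2))
  expect_equal(two$W, 1)
  expect_true(two$sphericity_ok)
  expect_true(two$skipped)
})

test_that("Mauchly holds its size under compound symmetry (simulation)", {
  withr::with_seed(44, {
    n <- 200; reps <- 500
    rej <- mean(replicate(reps, {
      subj <- rnorm(n, sd = 1)          # exchangeable covariance
      m <- subj + matrix(rnorm(n * 3), n, 3)
      mauchly_test(m)$p.value < 0.05
    }))
    expect_gt(rej, 0.03)
    expect_lt(rej, 0.08)
  })
})

test_that("Tukey contrasts behave at the edges and under relabelling", {
  same <- matrix(rnorm(30), 10, 3)[, c(1, 1, 1)]
  tp <- suppressWarnings(tukey_pairwise(same))
  expect_true(all(tp$q == 0))
  expect_true(all(is.na(tp$p_tukey) | tp$p_tukey == 1))
  withr::with_seed(45, {
    m <- random_rm_matrix(10, 3)
    colnames(m) <- c("baseline", "week2", "week4")
    tp <- tukey_pairwise(m)
    swapped <- m[, c(1, 3, 2)]
    ts <- tukey_pairwise(swapped)
    # estimates flip/relabel but p-values are the same set
    expect_equal(sort(unname(ts$p_tukey)), sort(unname(tp$p_tukey)),
                 tolerance = 1e-12)
    # conservativeness: Tukey p >= paired-t p with common error term
    fit <- rm_anova(m)
    for (j in seq_len(3)) {
      pair <- utils::combn(3, 2)[, j]
      tstat <- abs(mean(m[, pair[2]]) - mean(m[, pair[1]])) /
        sqrt(2 * fit$ms_error / nrow(m))
      p_t <- 2 * stats::pt(tstat, fit$df_den, lower.tail = FALSE)
      expect_gte(tp$p_tukey[j] + 1e-12, p_t)
    }
  })
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.01, 17)), rep(0.01, 17))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "dbm_bad_argument")
  withr::with_seed(46, {
    for (i in 1:20) {
      p <- runif(sample(1:30, 1))^sample(1:3, 1)
      adj <- bh_fdr(p)
      expect_equal(adj, oracle_bh(p), tolerance = 1e-14)
      expect_true(all(adj >= p - 1e-15))
      # permutation equivariance
      perm <- sample(length(p))
      expect_equal(bh_fdr(p[perm]), adj[perm], tolerance = 1e-14)
    }
  })
})

test_that("analyze_marker reports F under sphericity and W otherwise", {
  withr::with_seed(47, {
    m <- matrix(rnorm(45, mean = rep(c(0, 1, 2), each = 15)), 15, 3,
                dimnames = list(NULL, c("baseline", "week2", "week4")))
    res <- analyze_marker(m)
    expect_equal(res$statistic_kind, "F")
    expect_equal(res$direction, "+")
    expect_equal(res$p_fdr, res$p_raw)
    expect_lte(res$p_raw, 1)
    expect_gte(res$p_fdr, res$p_raw)
    # strongly non-spherical data: one difference variance blown up
    base <- rnorm(15)
    ns <- cbind(base, base + rnorm(15, 0, 0.05), base + rnorm(15, 2, 3))
    colnames(ns) <- c("baseline", "week2", "week4")
    res2 <- analyze_marker(ns)
    expect_false(res2$sphericity_ok)
    expect_equal(res2$statistic_kind, "W")
    expect_equal(res2$statistic, res2$mauchly_W)
    # the Greenhouse-Geisser corrected F is stored regardless
    expect_true(is.finite(res2$p_gg))
    expect_true(res2$gg_epsilon <= 1 & res2$gg_epsilon >= 0.5)
    # k = 2 always reports F
    res3 <- analyze_marker(matrix(rnorm(20), 10, 2))
    expect_equal(res3$statistic_kind, "F")
  })
})

test_that("analyze_markers adjusts within condition and flags directions", {
  ch <- simulate_cohort(cohort_config(seed = 19))
  res <- suppressWarnings(analyze_markers(ch$markers))
  tab <- tibble::as_tibble(res)
  expect_true(all(tab$p_fdr >= tab$p_raw - 1e-15))
  expect_true(all(tab$df_num == 2L))
  expect_true(all(tab$df_den == (tab$n - 1L) * 2L))
  expect_true(all(tab$direction %in% c("+", "-", "n/a")))
  # direction only claimed when FDR-significant
  expect_true(all(tab$direction[tab$p_fdr >= 0.05] == "n/a"))
  # glance/tidy surfaces
  fits <- attr(res, "fits")
  g <- glance(fits[[1]])
  expect_s3_class(g, "tbl_df")
  expect_equal(nrow(g), 1L)
  expect_equal(nrow(tidy(fits[[1]])), 3L)
})

test_that("clinical MADRS rules reproduce the printed cut points", {
  expect_true(responder_filter(30, 21))
  expect_false(responder_filter(30, 22))
  expect_true(responder_filter(40, 20))
  expect_error(responder_filter(0, 5), class = "dbm_bad_argument")

  expect_equal(madrs_severity(c(35, 34, 20, 19, 7, 6)),
               c("severe", "moderate", "moderate", "mild", "mild", "asymptomatic"))
  expect_error(madrs_severity(61), class = "dbm_bad_argument")
  expect_error(madrs_severity(12.5), class = "dbm_bad_argument")

  expect_equal(eligibility_filter(c(19, 20, 45)), c(FALSE, TRUE, TRUE))
})
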