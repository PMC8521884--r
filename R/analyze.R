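# Per-marker omnibus analysis and the full results table, plus the
# MADRS-based eligibility, responder and severity rules.

#' Analyse one visit matrix
#'
#' Runs Mauchly's sphericity test and the repeated-measures ANOVA on a
#' complete subject-by-visit matrix.  When sphericity holds, the reported
#' row statistic is F with its p-value; when it is violated, the reported
#' statistic is Mauchly's W with the sphericity p-value — the reporting
#' convention this pipeline reproduces — while the Greenhouse–Geisser
#' corrected F is always computed and stored as a robustness field, since
#' using the sphericity statistic as the effect test is unconventional.
#' Tukey HSD pairwise contrasts on the common error term are attached.
#'
#' The direction flag is `"+"`/`"-"` by the sign of the week-4 minus
#' baseline mean when the (possibly FDR-adjusted) reported p-value is below
#' `alpha`, else `"n/a"`.  Within [analyze_markers()] the flag is set after
#' FDR adjustment across the marker family; standalone, the raw p is used.
#'
#' @param x A [visit_matrix()] (or numeric matrix / all-numeric data frame).
#' @param alpha Significance level (default 0.05).
#' @param marker,condition Optional labels carried into the result.
#' @return A `marker_anova` object.
#' @export
#' @examples
#' m <- matrix(rnorm(36, mean = rep(c(0, 1, 2), each = 12)), 12, 3,
#'             dimnames = list(NULL, c("baseline", "week2", "week4")))
#' analyze_marker(m)
analyze_marker <- function(x, alpha = 0.05, marker = NA_character_,
                           condition = NA_character_) {
  m <- as_rm_matrix(x)
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  fit <- rm_anova(m)
  # with n <= k the contrast covariance is singular and sphericity is not
  # testable; fall back to the uncorrected F and record the W as missing
  sph <- tryCatch(
    mauchly_test(m, alpha = alpha),
    dbm_insufficient_n = function(e) {
      list(W = NA_real_, p.value = NA_real_, sphericity_ok = TRUE,
           df = NA_integer_, skipped = TRUE)
    }
  )
  eps <- gg_epsilon(m)
  p_gg <- if (is.finite(fit$statistic)) {
    pf(fit$statistic, eps * fit$df_num, eps * fit$df_den, lower.tail = FALSE)
  } else {
    fit$p.value
  }
  if (sph$sphericity_ok) {
    kind <- "F"
    stat <- fit$statistic
    p_raw <- fit$p.value
  } else {
    kind <- "W"
    stat <- sph$W
    p_raw <- sph$p.value
  }
  pair <- tukey_pairwise(m, fit$ms_error, fit$df_den)
  res <- structure(
    list(marker = marker, condition = condition,
         statistic_kind = kind, statistic = stat,
         df_num = fit$df_num, df_den = fit$df_den,
         p_raw = p_raw, p_fdr = p_raw,
         sphericity_ok = sph$sphericity_ok,
         mauchly_W = sph$W, mauchly_p = sph$p.value,
         f_statistic = fit$statistic, f_p = fit$p.value,
         gg_epsilon = eps, p_gg = p_gg,
         means = fit$means, n = fit$n, k = fit$k,
         alpha = alpha, pairwise = pair,
         direction = "n/a"),
    class = "marker_anova"
  )
  res$direction <- direction_flag(res)
  res
}

direction_flag <- function(res) {
  if (!is.na(res$p_fdr) && res$p_fdr < res$alpha) {
    delta <- res$means[length(res$means)] - res$means[1]
    if (delta > 0) "+" else if (delta < 0) "-" else "n/a"
  } else {
    "n/a"
  }
}

#' @export
print.marker_anova <- function(x, ...) {
  cat(sprintf(
    "<marker_anova>%s sphericity %s; %s = %.4g, p = %.4g (FDR %.4g), direction %s\n",
    if (is.na(x$marker)) "" else paste0(" ", x$marker),
    ifelse(x$sphericity_ok, "held", "violated"),
    x$statistic_kind, x$statistic, x$p_raw, x$p_fdr, x$direction))
  invisible(x)
}

#' Analyse every marker in a tidy marker table
#'
#' For each stimulus condition and marker: bins assessments into visits,
#' applies the complete-case rule, runs [analyze_marker()], and adjusts the
#' reported p-values with Benjamini–Hochberg FDR.  The FDR family is the
#' set of omnibus tests within one stimulus condition (default, matching a
#' per-condition results layout) or the whole table.
#'
#' @param markers Tidy marker table (`subject_id`, `study_day`,
#'   `stimulus_class`, `marker`, `value`).
#' @param alpha Significance level (default 0.05).
#' @param fdr_family `"condition"` (default) or `"table"`.
#' @return A `marker_results` tibble, one row per condition and marker,
#'   with the per-marker `marker_anova` objects in the `"fits"` attribute.
#'   Condition-marker pairs with too few complete cases are dropped with a
#'   warning.
#' @export
analyze_markers <- function(markers, alpha = 0.05,
                            fdr_family = c("condition", "table")) {
  fdr_family <- match.arg(fdr_family)
  needed <- c("subject_id", "study_day", "stimulus_class", "marker", "value")
  missing <- setdiff(needed, names(markers))
  if (length(missing)) {
    abort(sprintf("marker table lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "dbm_bad_argument")
  }
  conditions <- intersect(stimulus_classes(), unique(markers$stimulus_class))
  marker_names <- intersect(marker_catalog(), unique(markers$marker))
  fits <- list()
  skipped <- character()
  for (cond in conditions) {
    for (mk in marker_names) {
      d <- markers[markers$stimulus_class == cond & markers$marker == mk, ]
      vm <- tryCatch(visit_matrix(d), dbm_insufficient_n = function(e) NULL)
      if (is.null(vm)) {
        skipped <- c(skipped, sprintf("%s/%s", cond, mk))
        next
      }
      fits[[sprintf("%s.%s", cond, mk)]] <-
        analyze_marker(vm, alpha = alpha, marker = mk, condition = cond)
    }
  }
  if (length(skipped)) {
    warn(sprintf("skipped (too few complete cases): %s",
                 paste(skipped, collapse = ", ")))
  }
  if (!length(fits)) {
    abort("no condition/marker combination had enough complete cases.",
          class = "dbm_insufficient_n")
  }
  tab <- purrr::map_dfr(fits, glance_marker_anova_row)
  fam <- if (fdr_family == "condition") tab$condition else rep("all", nrow(tab))
  tab$p_fdr <- unsplit(lapply(split(tab$p_raw, fam), bh_fdr), fam)
  for (i in seq_len(nrow(tab))) {
    fits[[i]]$p_fdr <- tab$p_fdr[i]
    fits[[i]]$direction <- direction_flag(fits[[i]])
  }
  tab$direction <- vapply(fits, function(f) f$direction, character(1))
  tab <- order_results(tab)
  structure(tab, class = c("marker_results", class(tab)),
            fits = fits, alpha = alpha, fdr_family = fdr_family)
}

glance_marker_anova_row <- function(f) {
  tibble::tibble(
    condition = f$condition, marker = f$marker, n = f$n,
    sphericity = f$sphericity_ok, statistic_kind = f$statistic_kind,
    statistic = f$statistic, df_num = f$df_num, df_den = f$df_den,
    p_raw = f$p_raw, p_fdr = f$p_fdr, direction = f$direction,
    mauchly_W = f$mauchly_W, mauchly_p = f$mauchly_p,
    f_statistic = f$f_statistic, f_p = f$f_p,
    gg_epsilon = f$gg_epsilon, p_gg = f$p_gg
  )
}

order_results <- function(tab) {
  tab[order(match(tab$condition, stimulus_classes()),
            match(tab$marker, marker_catalog())), , drop = FALSE]
}

#' Pairwise contrasts from a results table
#'
#' @param results A `marker_results` table from [analyze_markers()].
#' @return Tidy tibble of Tukey contrasts for every condition and marker.
#' @export
pairwise_contrasts <- function(results) {
  fits <- attr(results, "fits")
  if (is.null(fits)) {
    abort("`results` carries no fitted objects.", class = "dbm_bad_argument")
  }
  purrr::map_dfr(fits, function(f) {
    dplyr::mutate(f$pairwise, condition = f$condition, marker = f$marker,
                  .before = 1)
  })
}

# ---- MADRS rules -----------------------------------------------------------

#' Responder rule
#'
#' A subject responds when the MADRS total drops by at least
#' `min_reduction` (default 30%) from baseline to week 4:
#' `(baseline - week4) / baseline >= 0.30`.
#'
#' @param madrs_baseline Positive baseline totals.
#' @param madrs_week4 Week-4 totals (>= 0).
#' @param min_reduction Required proportional reduction (default 0.30).
#' @return Logical vector: `TRUE` for included responders.
#' @export
#' @examples
#' responder_filter(c(30, 30, 40), c(21, 22, 20))
responder_filter <- function(madrs_baseline, madrs_week4, min_reduction = 0.30) {
  if (!is.numeric(madrs_baseline) || any(is.na(madrs_baseline)) ||
      any(madrs_baseline <= 0)) {
    abort("`madrs_baseline` must be positive.", class = "dbm_bad_argument")
  }
  if (!is.numeric(madrs_week4) || any(is.na(madrs_week4)) || any(madrs_week4 < 0)) {
    abort("`madrs_week4` must be non-negative.", class = "dbm_bad_argument")
  }
  (madrs_baseline - madrs_week4) / madrs_baseline >= min_reduction
}

#' MADRS severity band
#'
#' Validated clinical cut points: severe (> 34), moderate (20–34), mild
#' (7–19), asymptomatic (< 7).
#'
#' @param score Integer MADRS totals in `[0, 60]`.
#' @return Character vector of bands.
#' @export
#' @examples
#' madrs_severity(c(35, 34, 20, 19, 7, 6))
madrs_severity <- function(score) {
  if (!is.numeric(score) || any(is.na(score)) || any(score < 0 | score > 60) ||
      any(score != round(score))) {
    abort("`score` must be integer MADRS totals in [0, 60].",
          class = "dbm_bad_argument")
  }
  dplyr::case_when(
    score > 34 ~ "severe",
    score >= 20 ~ "moderate",
    score >= 7 ~ "mild",
    TRUE ~ "asymptomatic"
  )
}

#' Eligibility rule
#'
#' Study entry requires a baseline MADRS total of at least 20.
#'
#' @param madrs_baseline MADRS totals.
#' @param min_score Eligibility threshold (default 20).
#' @return Logical vector: `TRUE` for eligible.
#' @export
#' @examples
#' eligibility_filter(c(19, 20, 45))
eligibility_filter <- function(madrs_baseline, min_score = 20) {
  if (!is.numeric(madrs_baseline) || any(is.na(madrs_baseline))) {
    abort("`madrs_baseline` must be numeric.", class = "dbm_bad_argument")
  }
  madrs_baseline >= min_score
}
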