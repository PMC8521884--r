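# Repeated-measures machinery: one-way within-subject ANOVA, Mauchly's
# sphericity test with the Greenhouse-Geisser correction, Tukey HSD pairwise
# contrasts on the common error term, and Benjamini-Hochberg adjustment.

# Accepts a visit_matrix, a plain all-numeric data frame, or a matrix.
as_rm_matrix <- function(x) {
  if (inherits(x, "visit_matrix")) return(vm_values(x))
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    return(as.matrix(x[num]))
  }
  as.matrix(x)
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject decomposition of a complete n-subject by k-visit
#' matrix: `SS_time` with `k - 1` df, `SS_error = SS_total - SS_subjects -
#' SS_time` with `(n - 1)(k - 1)` df, `F = MS_time / MS_error`, p from the F
#' distribution.  Identical columns give F = 0; a zero error variance gives
#' an infinite F with p = 0 and a degenerate-data warning.
#'
#' @param x A [visit_matrix()], numeric matrix, or all-numeric data frame
#'   (rows = subjects, columns = time points), complete, with n >= 2 and
#'   k >= 2.
#' @return An `rm_anova` object with `statistic`, `df_num`, `df_den`,
#'   `p.value`, the SS table and the column means.
#' @export
#' @examples
#' m <- matrix(rnorm(54), 18, 3)
#' rm_anova(m)
rm_anova <- function(x) {
  m <- as_rm_matrix(x)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) {
    abort("need a complete matrix with >= 2 subjects and >= 2 time points.",
          class = "dbm_insufficient_n")
  }
  if (anyNA(m)) abort("matrix has missing cells.", class = "dbm_bad_argument")
  gm <- mean(m)
  col_means <- colMeans(m)
  row_means <- rowMeans(m)
  ss_time <- n * sum((col_means - gm)^2)
  ss_subj <- k * sum((row_means - gm)^2)
  ss_total <- sum((m - gm)^2)
  ss_error <- ss_total - ss_time - ss_subj
  df_num <- k - 1L
  df_den <- (n - 1L) * (k - 1L)
  ms_time <- ss_time / df_num
  ms_error <- ss_error / df_den
  if (ms_error <= .Machine$double.eps * max(1, ss_total)) {
    if (ss_time <= .Machine$double.eps * max(1, ss_total)) {
      f <- 0
      p <- 1
    } else {
      warn("zero within-subject error variance: degenerate data, F reported as Inf.")
      f <- Inf
      p <- 0
    }
  } else {
    f <- ms_time / ms_error
    p <- pf(f, df_num, df_den, lower.tail = FALSE)
  }
  structure(
    list(statistic = f, df_num = df_num, df_den = df_den, p.value = p,
         ss = tibble::tibble(
           term = c("time", "subjects", "error"),
           df = c(df_num, n - 1L, df_den),
           sumsq = c(ss_time, ss_subj, ss_error)
         ),
         ms_error = ms_error, means = col_means, n = n, k = k),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.4g, p = %.4g (n = %d)\n",
              x$df_num, x$df_den, x$statistic, x$p.value, x$n))
  invisible(x)
}

# Orthonormal contrast basis over k levels (k x (k-1)), via QR of the
# Helmert contrasts.
orthonormal_contrasts <- function(k) {
  qr.Q(qr(stats::contr.helmert(k)))
}

contrast_covariance <- function(m) {
  k <- ncol(m)
  M <- orthonormal_contrasts(k)
  S <- cov(m)
  t(M) %*% S %*% M
}

#' Mauchly's test of sphericity
#'
#' Tests equality of the variances of all pairwise time-point differences.
#' `W = det(M'SM) / (tr(M'SM) / (k - 1))^(k - 1)` with `S` the sample
#' covariance of the k repeated measures and `M` an orthonormal contrast
#' basis.  The p-value uses Box's chi-square approximation with
#' `f = k(k - 1)/2 - 1` df: `z = -(n - 1) rho log W` with scaling factor
#' `rho = 1 - (2(k-1)^2 + (k-1) + 2) / (6(k-1)(n-1))`, refined by the
#' standard second-order term `w2 (P(chi2_{f+4} > z) - P(chi2_f > z))`
#' (zero at k = 3).  With k = 2 there is a single difference variance, so
#' W is identically 1 and the test is skipped.
#'
#' @inheritParams rm_anova
#' @param alpha Sphericity level for the `sphericity_ok` verdict
#'   (default 0.05).
#' @return List with `W`, `p.value`, `sphericity_ok`, `df`, and `skipped`.
#' @export
mauchly_test <- function(x, alpha = 0.05) {
  m <- as_rm_matrix(x)
  n <- nrow(m)
  k <- ncol(m)
  if (k == 2L) {
    return(list(W = 1, p.value = NA_real_, sphericity_ok = TRUE,
                df = 0L, skipped = TRUE))
  }
  if (k < 2L || n <= k) {
    abort("Mauchly's test needs n > k >= 3.", class = "dbm_insufficient_n")
  }
  Tm <- contrast_covariance(m)
  W <- det(Tm) / (sum(diag(Tm)) / (k - 1))^(k - 1)
  q <- k - 1
  nn <- n - 1
  f <- k * q / 2 - 1
  rho <- 1 - (2 * q^2 + q + 2) / (6 * q * nn)
  w2 <- (q + 2) * (q - 1) * (q - 2) * (2 * q^3 + 6 * q^2 + 3 * k + 2) /
    (288 * (nn * q * rho)^2)
  stat <- -nn * rho * log(W)
  pr1 <- pchisq(stat, f, lower.tail = FALSE)
  pr2 <- pchisq(stat, f + 4, lower.tail = FALSE)
  p <- pr1 + w2 * (pr2 - pr1)
  list(W = as.numeric(W), p.value = as.numeric(p),
       sphericity_ok = p > alpha, df = f, skipped = FALSE)
}

#' Greenhouse–Geisser epsilon
#'
#' Sphericity departure estimate from the contrast-projected covariance:
#' `tr(T)^2 / ((k - 1) tr(T^2))`, in `[1/(k-1), 1]`.  Used for the
#' robustness-corrected F stored alongside the reported statistic.
#'
#' @inheritParams rm_anova
#' @return Epsilon estimate.
#' @export
gg_epsilon <- function(x) {
  m <- as_rm_matrix(x)
  k <- ncol(m)
  if (k == 2L) return(1)
  Tm <- contrast_covariance(m)
  as.numeric(sum(diag(Tm))^2 / ((k - 1) * sum(Tm^2)))
}

#' Tukey HSD pairwise contrasts between time points
#'
#' For each pair of visits, `q = |mean difference| / sqrt(MS_error / n)`
#' with the within-subject `MS_error` and its df as the common error term;
#' p-values come from the studentized-range distribution with `(k, df_den)`.
#' Tukey's procedure controls the familywise error rate across the
#' contrasts.  Estimates are later-minus-earlier mean differences.
#'
#' @inheritParams rm_anova
#' @param ms_error,df_den Error mean square and df; computed from `x` via
#'   [rm_anova()] when omitted.
#' @return Tibble `(contrast, estimate, q, p_tukey)`; with a degenerate
#'   (zero) error term the p-values are `NA` and a warning is raised.
#' @export
tukey_pairwise <- function(x, ms_error = NULL, df_den = NULL) {
  m <- as_rm_matrix(x)
  n <- nrow(m)
  k <- ncol(m)
  if (is.null(ms_error) || is.null(df_den)) {
    fit <- rm_anova(m)
    ms_error <- fit$ms_error
    df_den <- fit$df_den
  }
  cm <- colMeans(m)
  labs <- colnames(m) %||% paste0("t", seq_len(k))
  pairs <- utils::combn(k, 2)
  est <- cm[pairs[2, ]] - cm[pairs[1, ]]
  degenerate <- !is.finite(ms_error) || ms_error <= 0
  if (degenerate) {
    warn("degenerate error term: Tukey contrasts flagged, p not computed.")
    q <- ifelse(est == 0, 0, Inf)
    p <- rep(NA_real_, length(est))
  } else {
    q <- abs(est) / sqrt(ms_error / n)
    p <- ptukey(q, nmeans = k, df = df_den, lower.tail = FALSE)
  }
  tibble::tibble(
    contrast = sprintf("%s - %s", labs[pairs[2, ]], labs[pairs[1, ]]),
    estimate = as.numeric(est),
    q = as.numeric(q),
    p_tukey = as.numeric(p)
  )
}

#' Benjamini–Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone non-decreasing in rank and capped at
#' 1; never smaller than the raw p-value.  An empty input returns an empty
#' vector.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("`p` must be p-values in [0, 1].", class = "dbm_bad_argument")
  }
  p.adjust(p, method = "BH")
}
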