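# Independent oracles: brute-force implementations kept deliberately
# separate from the package's code paths.

# One-way within-subject ANOVA by explicit loops over cells.
oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- sum(m) / (n * k)
  ss_time <- 0
  for (j in seq_len(k)) {
    cm <- sum(m[, j]) / n
    ss_time <- ss_time + n * (cm - gm)^2
  }
  ss_subj <- 0
  for (i in seq_len(n)) {
    rm_ <- sum(m[i, ]) / k
    ss_subj <- ss_subj + k * (rm_ - gm)^2
  }
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_tot <- ss_tot + (m[i, j] - gm)^2
  ss_err <- ss_tot - ss_time - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  f <- (ss_time / df1) / (ss_err / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = pf(f, df1, df2, lower.tail = FALSE))
}

# Mauchly via the stats mlm machinery (independent code path).
oracle_mauchly <- function(m) {
  fit <- stats::lm(m ~ 1)
  ref <- stats::mauchly.test(fit, X = ~1)
  list(W = unname(ref$statistic), p = unname(ref$p.value))
}

# Benjamini-Hochberg step-up by explicit sort/cummin loops.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[o[r]] * m / r)
    adj[o[r]] <- val
    prev <- val
  }
  adj
}

# Upper tail of the studentized range distribution by direct double
# numerical integration over the scale mixture representation.
oracle_ptukey_upper <- function(q, k, df) {
  if (!is.finite(q)) return(0)
  if (q <= 0) return(1)
  inner <- function(x) {
    f <- function(z) stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - x))^(k - 1)
    k * stats::integrate(f, -Inf, Inf, rel.tol = 1e-11)$value
  }
  dens_s <- function(s) {
    exp(log(2) + df / 2 * log(df / 2) - lgamma(df / 2) +
          (df - 1) * log(s) - df * s^2 / 2)
  }
  val <- stats::integrate(function(ss) {
    vapply(ss, function(s) dens_s(s) * inner(q * s), numeric(1))
  }, 0, Inf, rel.tol = 1e-10)$value
  1 - val
}

random_rm_matrix <- function(n = NULL, k = NULL) {
  n <- n %||% sample(5:14, 1)
  k <- k %||% sample(3:5, 1)
  matrix(rnorm(n * k, mean = rep(rnorm(k, sd = 0.5), each = n)), n, k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
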