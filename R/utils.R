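# Internal helpers shared across modules.

clip <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

# Run `code` under a fixed RNG state when a seed is supplied, leaving the
# caller's RNG untouched; otherwise draw from the current stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Truncated normal by rejection; degenerates to the (clipped) mean at sd = 0.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) {
    return(rep(clip(mean, lower, upper), n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(max(2L * n, 10L), mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

is_scalar_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

assert_scalar_number <- function(x, name, min = -Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s.", name, format(min)),
          class = "dbm_bad_argument")
  }
  invisible(x)
}

# Deterministic child seeds for independent sub-streams, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.double(seed) * 48271 + 7907 * as.double(offset)) %% 2147483629
}
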