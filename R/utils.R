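# Internal helpers shared across the pipeline.

#' @importFrom data.table := .N .SD data.table as.data.table setorder setattr setnames rbindlist fwrite fread setDT copy
NULL

epochs_to_hours <- function(n) n / EPOCHS_PER_HOUR
hours_to_epochs <- function(h) as.integer(round(h * EPOCHS_PER_HOUR))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Truncated normal draw by rejection with a clamp fallback; sd = 0 returns
# the mean exactly (used by the sd-0 calibration mode of the generator).
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  for (i in seq_len(20)) {
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  pmin(pmax(x, lo), hi)
}

# Random composition of total `s` into `k` non-negative integer parts.
rand_composition <- function(s, k) {
  if (k == 1L) return(s)
  if (s == 0L) return(integer(k))
  cuts <- sort(sample.int(s + k - 1L, k - 1L))
  diff(c(0L, cuts, s + k - 1L)) - 1L
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

assert_prob_matrix <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stopf("transition matrix must be square")
  if (any(m < -tol) || any(m > 1 + tol))
    stopf("transition probabilities must lie in [0, 1]")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol))
    stopf("transition matrix rows must sum to 1 (max deviation %.3g)", max(abs(rs - 1)))
  invisible(m)
}
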