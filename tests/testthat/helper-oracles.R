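# Independent oracles. Each re-derives a quantity by the most literal
# method available (explicit scanning, closed forms, stats:: routines)
# and is kept free of the package's own code paths.

# Maximal runs of a logical vector by explicit scanning (no rle()).
scan_runs <- function(x) {
  n <- length(x)
  s <- integer(0); e <- integer(0); v <- logical(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    s <- c(s, i); e <- c(e, j); v <- c(v, x[i])
    i <- j + 1L
  }
  list(start = s, end = e, value = v)
}

# Literal re-implementation of the four window rules: per-run rewriting
# on a copied vector, then explicit segment accumulation.
oracle_windows <- function(stages, smooth_e = 20L, gap_e = 120L,
                           short_e = 360L, gap_le = FALSE) {
  wake <- stages == 0L
  r <- scan_runs(wake)
  for (k in seq_along(r$start))
    if (r$value[k] && (r$end[k] - r$start[k] + 1L) < smooth_e)
      wake[r$start[k]:r$end[k]] <- FALSE
  r <- scan_runs(wake)
  for (k in seq_along(r$start))
    if (!r$value[k] && (r$end[k] - r$start[k] + 1L) < smooth_e)
      wake[r$start[k]:r$end[k]] <- TRUE
  r <- scan_runs(wake)
  segs <- which(!r$value)
  if (!length(segs)) return(data.frame(start = integer(0), end = integer(0),
                                       kind = character(0)))
  out <- data.frame(start = r$start[segs[1]], end = r$end[segs[1]])
  for (k in segs[-1]) {
    gap <- r$start[k] - out$end[nrow(out)] - 1L
    merge <- if (gap_le) gap <= gap_e else gap < gap_e
    if (merge) out$end[nrow(out)] <- r$end[k]
    else out <- rbind(out, data.frame(start = r$start[k], end = r$end[k]))
  }
  out$kind <- ifelse(out$end - out$start + 1L < short_e, "short", "long")
  out
}

# Mutual information in bits via the symmetric identity
# I = H(rows) + H(cols) - H(joint); independent of the package's
# conditional-entropy decomposition.
oracle_mutual_information <- function(tab) {
  p <- tab / sum(tab)
  h <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  h(rowSums(p)) + h(colSums(p)) - h(as.vector(p))
}

# Textbook silhouette from the full distance matrix, double loop.
oracle_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  ks <- unique(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(ks[ks != labels[i]], function(k)
      mean(d[i, labels == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Adjusted Rand index from the pair-counting closed form.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
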