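# Independent oracles used by the unit and acceptance tests.

# Exhaustive maximum one-to-one band matching by recursion (small inputs).
oracle_match_count <- function(a, b, tol) {
  if (!length(a) || !length(b)) return(0L)
  best <- oracle_match_count(a[-1], b, tol)  # leave a[1] unmatched
  for (j in seq_along(b)) {
    if (abs(a[1] - b[j]) <= tol) {
      best <- max(best, 1L + oracle_match_count(a[-1], b[-j], tol))
    }
  }
  best
}

# Monte-Carlo band-throwing oracle for the Sulston score. Bands are thrown
# uniformly on a circular axis of `gellen` distinguishable positions; the
# score models, for each band of the smaller profile, the event "some band
# of the larger profile lies within tolerance" (counted with multiplicity).
oracle_sulston_mc <- function(n_low, n_high, shared, tol, gellen, trials, seed) {
  set.seed(seed)
  a <- matrix(runif(trials * n_low, 0, gellen), trials, n_low)
  b <- matrix(runif(trials * n_high, 0, gellen), trials, n_high)
  hits <- matrix(FALSE, trials, n_low)
  for (i in seq_len(n_low)) {
    m <- rep(FALSE, trials)
    for (j in seq_len(n_high)) {
      d <- abs(a[, i] - b[, j])
      d <- pmin(d, gellen - d)
      m <- m | (d <= tol)
    }
    hits[, i] <- m
  }
  cnt <- rowSums(hits)
  p_hat <- mean(cnt >= shared)
  list(p = p_hat, se = sqrt(max(p_hat * (1 - p_hat), 1e-12) / trials))
}

# Exhaustive minimum interval cover: smallest clone subset whose spans
# cover [min(start), max(end)] end to end without gaps.
oracle_min_cover_size <- function(starts, ends) {
  n <- length(starts)
  lo <- min(starts); hi <- max(ends)
  best <- Inf
  for (mask in seq_len(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) >= best) next
    s <- starts[sel]; e <- ends[sel]
    ord <- order(s)
    s <- s[ord]; e <- e[ord]
    if (s[1] > lo || max(e) < hi) next
    reach <- e[1]; ok <- TRUE
    for (k in seq_along(s)[-1]) {
      if (s[k] > reach) { ok <- FALSE; break }
      reach <- max(reach, e[k])
    }
    if (ok && reach >= hi) best <- length(sel)
  }
  best
}

# N50/L50 by direct enumeration.
oracle_n50 <- function(lengths) {
  len <- sort(lengths, decreasing = TRUE)
  total <- sum(len)
  k <- which(cumsum(len) >= total / 2)[1]
  list(n50 = len[k], l50 = k)
}
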