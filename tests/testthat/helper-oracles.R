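# Independent re-implementations used as oracles. Deliberately written from
# the definitions (explicit formulas, exhaustive enumeration), not by calling
# the package code paths they check.

# Leave-one-out outlier oracle: among >= 4 finite values with CV at or above
# the threshold, drop the single value minimising the CV of the remainder,
# but only if it deviates from the others' mean by more than k of their sd.
oracle_outlier_retained <- function(values, cv_threshold = 0.60, k = 2.0) {
  v <- values[is.finite(values) & values > 0]
  n <- length(v)
  cv_of <- function(x) {
    m <- sum(x) / length(x)
    s <- sqrt(sum((x - m)^2) / (length(x) - 1))
    s / m
  }
  if (n < 4 || cv_of(v) < cv_threshold) return(v)
  cvs <- sapply(seq_len(n), function(i) cv_of(v[-i]))
  i <- which.min(cvs)
  rest <- v[-i]
  if (abs(v[i] - mean(rest)) > k * sqrt(sum((rest - mean(rest))^2) /
                                          (length(rest) - 1))) {
    return(rest)
  }
  v
}

# Welch two-sample t-test, two-sided, from the formula.
oracle_welch_p <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# Two-sided Fisher exact p by exhaustive enumeration over all 2x2 tables
# with the observed margins, summing the probabilities of tables no more
# probable than the observed one.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  N <- sum(tab)
  ks <- max(0, r1 + c1 - N):min(r1, c1)
  logp <- lchoose(c1, ks) + lchoose(N - c1, r1 - ks) - lchoose(N, r1)
  p <- exp(logp)
  p_obs <- p[ks == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Shannon entropy in bits.
oracle_entropy <- function(q) {
  q <- q[q > 0]
  -sum(q * log2(q))
}

# Exact probability that a uniform-random 8-mer is called SD-positive
# (>= min_matches position-wise matches to the consensus, or a consecutive
# run of >= min_run matches), by enumeration over all 4^8 sequences. The
# per-position match indicator is iid Bernoulli(1/4) whatever the consensus
# says, so enumerating match/mismatch patterns suffices.
oracle_site_positive_rate <- function(len = 8, min_matches = 5, min_run = 4) {
  patterns <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), len)))
  hit <- apply(patterns, 1, function(h) {
    r <- rle(h)
    runmax <- if (any(r$values)) max(r$lengths[r$values]) else 0
    sum(h) >= min_matches || runmax >= min_run
  })
  nmatch <- rowSums(patterns)
  probs <- (1 / 4)^nmatch * (3 / 4)^(len - nmatch)
  sum(probs[hit])
}

random_windows <- function(n, len = 20, seed = 1,
                           prob = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  set.seed(seed)
  apply(matrix(sample(names(prob), n * len, TRUE, prob = prob), nrow = n),
        1, paste, collapse = "")
}
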