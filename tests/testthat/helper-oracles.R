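# Independent brute-force oracles, deliberately written from the
# definitions and kept free of package internals.

# Weighted KS running sum by explicit walk over every ranked position.
oracle_es <- function(stats, set, alpha = 1) {
  ord <- order(-stats, names(stats))
  s <- stats[ord]
  inset <- names(s) %in% set
  n <- length(s)
  m <- sum(inset)
  w <- abs(s)^alpha
  denom_hit <- sum(w[inset])
  run <- 0
  up <- 0
  dn <- 0
  for (i in seq_len(n)) {
    if (inset[i]) {
      run <- run + if (denom_hit == 0) 1 / m else w[i] / denom_hit
    } else {
      run <- run - 1 / (n - m)
    }
    if (run > up) up <- run
    if (run < dn) dn <- run
  }
  if (up + dn >= -1e-9) up else dn   # equal magnitudes resolve positive
}

# Exact hypergeometric upper tail by direct enumeration of choose() terms.
oracle_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Gaussian-kernel CDF transform in plain R.
oracle_kcdf <- function(x, bw) {
  z <- x
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      z[i, j] <- mean(pnorm((x[i, j] - x[i, ]) / bw[i]))
    }
  }
  z
}

# Hand Benjamini-Hochberg: q_(i) = min_{j>=i} m p_(j)/j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
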