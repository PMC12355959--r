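# Independent brute-force oracles used across the suite.

# Benjamini-Hochberg step-up computed literally from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, mapped back to the input order.
bh_stepup_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(p[ord][i:m] * m / (i:m))
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Upper-tail hypergeometric probability P(X >= k) by direct enumeration
# of the probability mass function.
hyper_tail_enum <- function(k, K, N, n) {
  xs <- max(0, k):min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs) / choose(N, n))
}

# Reliability filter by literal per-feature counting.
reliability_filter_bruteforce <- function(values, groups, min_fraction) {
  keep <- logical(nrow(values))
  for (i in seq_len(nrow(values))) {
    for (g in unique(groups)) {
      cols <- which(groups == g)
      if (sum(!is.na(values[i, cols])) >= ceiling(min_fraction * length(cols))) {
        keep[i] <- TRUE
      }
    }
  }
  keep
}

# Equal-variance two-sample t-test from the textbook formulas.
student_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# A tiny noiseless melting experiment for fit tests.
make_clean_series <- function(a, b, plateau, gradient = tpp_gradient()) {
  melt_model(gradient, a, b, plateau)
}
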