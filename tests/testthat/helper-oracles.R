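# Independent brute-force oracles, kept deliberately naive so they
# stay independent of the implementation paths they check.

# median-of-ratios by direct looping over the definition
bf_size_factors <- function(m) {
  geo <- apply(m, 1, function(x) prod(x)^(1 / length(x)))
  ok <- apply(m, 1, function(x) all(x > 0))
  sapply(seq_len(ncol(m)), function(j) {
    stats::median(m[ok, j] / geo[ok])
  })
}

# BH step-up exactly as defined: adj_(i) = min_{j>=i} p_(j) * m / j
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# hypergeometric upper tail by full-support enumeration
bf_hyper_tail <- function(N, K, n, k) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# small default experiment used by several tests
tiny_config <- function(seed = 1, ...) {
  sim_config(n_genes = 300, n_terms = 30, term_size_range = c(5, 10),
             n_de_genes = 60, n_planted_terms = 2, seed = seed, ...)
}
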