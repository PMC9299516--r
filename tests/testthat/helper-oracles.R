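# Independent brute-force oracles used to cross-check package routines.

# Benjamini-Hochberg step-up, written out directly from the definition:
# adj_(i) = min_{j >= i} min(1, n * p_(j) / j) on the sorted p-values.
bh_step_up <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  cur <- 1
  for (i in n:1) {
    cur <- min(cur, n * p[o[i]] / i)
    adj[o[i]] <- cur
  }
  adj
}

# Exact hypergeometric upper tail P(X >= k) by explicit enumeration.
hyper_tail <- function(k, m, N, K) {
  i <- k:min(m, K)
  sum(choose(m, i) * choose(N - m, K - i)) / choose(N, K)
}

# Per-cell brute-force reactive fraction (the definition, no vectorization).
brute_fraction <- function(delta_f_values, threshold_value) {
  n_reactive <- 0L
  for (v in delta_f_values) {
    if (v > threshold_value) n_reactive <- n_reactive + 1L
  }
  n_reactive / length(delta_f_values)
}
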