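# Independent oracles and small fixture builders used across tests.

# Exact two-sided Mann-Whitney p-value by full enumeration of all rank
# placements of the first sample among the pooled ranks (tie-free inputs).
mw_enumerate_p <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Textbook Benjamini-Hochberg step-up with cumulative minimum.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Tiny deterministic library: n_genes genes x k elements plus NTCs.
tiny_library <- function(n_genes = 3, k = 2, n_ntc = 4) {
  simulate_library(n_genes, k, n_ntc = n_ntc, seed = 99)
}

# Hand-built count table over a tiny library, all counts positive.
tiny_counts <- function(library, seed = 7, replicates = 2) {
  n <- nrow(library)
  samples <- as.vector(outer(c("T0", "vehicle", "drug"),
                             paste0("_r", seq_len(replicates)), paste0))
  m <- withr::with_seed(seed, {
    matrix(rpois(n * length(samples), 100) + 1L, nrow = n,
           dimnames = list(library$element_id, samples))
  })
  count_table(m)
}
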