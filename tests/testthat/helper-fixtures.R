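# Shared fixtures and independent oracles. Everything here is deliberately
# written as straight-line brute force, independent of the package internals
# it checks.

# A config with every planted effect switched off: a global null.
null_config <- function(seed, n_genes = 2000, ...) {
  sim_config(
    n_genes = n_genes, n_age_genes = 0, n_cluster_blocks = 0,
    covariate_effects = data.frame(covariate = character(),
                                   n_genes = integer(), log2fc = numeric()),
    noncoding_fraction = 0, seed = seed, ...
  )
}

# A small cohort for fast unit tests.
small_config <- function(seed, ...) {
  sim_config(
    n_genes = 300, n_age_genes = 60, n_cluster_blocks = 1,
    cluster_block_size = 50,
    covariate_effects = data.frame(covariate = "sex", n_genes = 30, log2fc = 1),
    group_sizes = c(HC = 20, MDD_untreated = 40),
    noncoding_fraction = 0.1, seed = seed, ...
  )
}

# Brute-force step-up BH: for each p_i, the smallest p_j*m/rank_j over all
# thresholds j with p_j >= p_i, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- vapply(p, function(t) {
      if (t >= pi) t * m / sum(p <= t) else Inf
    }, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# Exhaustive two-sided Fisher p by direct lchoose arithmetic over the
# support of tables sharing the observed margins.
fisher_brute <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  support <- max(0, r1 + c1 - N):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(N - c1, r1 - support) - lchoose(N, r1)
  probs <- exp(logp)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Double-loop TOM on an adjacency matrix with zero diagonal.
tom_brute <- function(A) {
  n <- nrow(A)
  out <- diag(n)
  k <- rowSums(A)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    L <- sum(A[i, ] * A[, j])
    out[i, j] <- (L + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  dimnames(out) <- dimnames(A)
  out
}

# Upper-tail hypergeometric by enumerating every n-subset of a population of
# size N with K marked elements.
ora_brute <- function(N, K, n, k) {
  pop <- c(rep(1, K), rep(0, N - K))
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(ix) sum(pop[ix]))
  mean(hits >= k)
}
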