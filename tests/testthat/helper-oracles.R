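# Independent oracles used by the test suite.

# Brute-force pre-ranked GSEA enrichment score: explicit running-sum
# array over every position of the ranked list, no shortcuts.  Kept
# deliberately independent of the package's candidate-point
# implementation.
oracle_es <- function(ranked_scores, set_genes, weight = 1) {
  genes <- names(ranked_scores)
  hit <- genes %in% set_genes
  N <- length(genes)
  k <- sum(hit)
  stopifnot(k > 0, k < N)
  w <- abs(as.numeric(ranked_scores))^weight * hit
  W <- sum(w)
  if (W <= 0) {
    w[hit] <- 1
    W <- k
  }
  p_hit <- cumsum(w) / W
  p_miss <- cumsum(!hit) / (N - k)
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

# Random (ranked list, gene set) instance for oracle-equivalence checks.
random_gsea_instance <- function(n_max = 50) {
  N <- sample(5:n_max, 1)
  scores <- stats::setNames(stats::rnorm(N), sprintf("g%03d", seq_len(N)))
  k <- sample(seq_len(N - 1), 1)
  list(ranked = rank_genes(scores),
       set = sample(names(scores), k))
}

# Small paired cohort with a strong planted signal, for fast unit tests.
small_cohort <- function(seed = 1, n_genes = 600, n_planted = 60,
                         n_per_class = 12, effect = 2) {
  simulate_cohort(n_genes = n_genes, n_planted_R = n_planted,
                  n_planted_S = n_planted, n_responders = n_per_class,
                  n_nonresponders = n_per_class, effect_size = effect,
                  seed = seed)
}
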