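# Single-sample gene-set enrichment (ssGSEA, Barbie-style): rank-based,
# so the score is invariant under monotone relabelings of expression.

#' Single-sample gene-set enrichment score
#'
#' Rank-normalizes one expression column (top gene gets rank weight N),
#' then accumulates the difference between the weighted empirical CDF of
#' in-set genes (weights `rank^exponent`) and the unweighted CDF of
#' out-of-set genes along the descending ranking.  The integrated
#' difference is divided by N so scores are comparable across universes.
#'
#' @param expr_column named numeric vector (gene -> expression) with at
#'   least two distinct values.
#' @param gene_set character vector of gene ids; must intersect the
#'   expressed genes and not cover all of them.
#' @param exponent rank-weighting exponent; default 0.25.
#' @return scalar enrichment score.
#' @export
ssgsea_score <- function(expr_column, gene_set, exponent = 0.25) {
  if (is.null(names(expr_column))) stop("expr_column must be named by gene id")
  if (anyNA(expr_column)) stop("expr_column contains missing values")
  if (length(unique(expr_column)) < 2L) {
    stop("all expression values are equal; no ranking defined")
  }
  genes <- names(expr_column)
  N <- length(genes)
  hit <- genes %in% .as_genes(gene_set)
  k <- sum(hit)
  if (k == 0L) stop("gene set does not intersect the expressed genes")
  if (k == N) stop("gene set covers all expressed genes")

  ord <- order(-expr_column, genes, method = "radix")
  hit <- hit[ord]
  rnk <- (N:1)^exponent
  w <- ifelse(hit, rnk, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!hit) / (N - k)
  sum(p_in - p_out) / N
}
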