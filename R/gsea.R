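# Pre-ranked GSEA engine: weighted Kolmogorov-Smirnov-like running-sum
# enrichment score, gene-set permutation null, normalized enrichment
# score, and the RS (sensitive-minus-resistant) score.
#
# The running sum only changes slope at hit positions, so the extreme
# deviation is attained either at a hit or at the position immediately
# before a hit; the implementation therefore evaluates only those O(k)
# candidates instead of walking all N positions.

as_ranked_list <- function(x) {
  if (inherits(x, "ranked_list")) return(x)
  rank_genes(x)
}

#' Rank a profile of per-gene scores
#'
#' Sorts a named score vector (e.g. one column of a delta matrix or one
#' level-5 z-score profile) in descending score order; ties are broken by
#' ascending gene id so the ranking is deterministic.  Genes with
#' non-finite scores are excluded with a warning.
#'
#' @param scores named numeric vector (gene -> score).
#' @return a `ranked_list`: the sorted named vector.
#' @export
rank_genes <- function(scores) {
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("scores must be named by gene id")
  }
  if (anyDuplicated(names(scores))) {
    stop("duplicate gene id in scores: ",
         names(scores)[duplicated(names(scores))][1L])
  }
  bad <- !is.finite(scores)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with non-finite scores excluded", call. = FALSE)
    scores <- scores[!bad]
  }
  if (length(scores) < 2L) stop("need at least 2 genes with finite scores")
  ord <- order(-scores, names(scores), method = "radix")
  structure(scores[ord], class = "ranked_list")
}

# Core running-sum extremum for sorted hit positions `pos` in a ranked
# list of length N with per-position weights `aw` (= |score|^weight).
# All-zero hit weights fall back to uniform 1/k increments so the score
# stays defined on degenerate (flat) profiles.
.es_core <- function(pos, aw, N) {
  k <- length(pos)
  wv <- aw[pos]
  W <- sum(wv)
  if (W <= 0) {
    wv <- rep.int(1, k)
    W <- k
  }
  cumW <- cumsum(wv) / W
  miss <- (pos - seq_len(k)) / (N - k)
  top <- cumW - miss                      # deviation at each hit
  bot <- c(0, cumW[-k]) - miss            # deviation just before each hit
  cp <- c(pos, pos - 1L)
  cv <- c(top, bot)
  keep <- cp >= 1L
  cp <- cp[keep]
  cv <- cv[keep]
  a <- abs(cv)
  mx <- max(a)
  cand <- which(a == mx)
  unname(cv[cand[which.min(cp[cand])]])
}

# Seeded draws of `n_perm` random hit-position sets of size k (columns,
# sorted), shared across calls so cached and uncached screening agree.
.draw_null_positions <- function(N, k, n_perm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- vapply(seq_len(n_perm), function(b) sort.int(sample.int(N, k)),
              integer(k))
  matrix(m, nrow = k)
}

#' Pre-ranked GSEA enrichment score
#'
#' Walks the descending ranked list; at a hit the running sum increases by
#' `|score|^weight / sum(|score|^weight over hits)`, at a miss it
#' decreases by `1 / (N - k)`.  The enrichment score (ES) is the running
#' deviation of maximum absolute value, with its sign; `|ES| <= 1`.
#'
#' @param ranked a `ranked_list` (or named score vector, ranked on the fly).
#' @param gene_set character vector (or [gene_signature] object) of gene ids.
#' @param weight exponent on the absolute score in the hit increments;
#'   default 1.
#' @return the enrichment score, a scalar in `[-1, 1]`.
#' @export
prerank_es <- function(ranked, gene_set, weight = 1) {
  ranked <- as_ranked_list(ranked)
  genes <- names(ranked)
  N <- length(genes)
  pos <- which(genes %in% .as_genes(gene_set))
  if (length(pos) == 0L) stop("gene set does not intersect the ranked list")
  if (length(pos) == N) {
    stop("gene set covers the entire ranked list; miss increment undefined")
  }
  aw <- abs(unclass(ranked))^weight
  .es_core(pos, aw, N)
}

#' Normalized enrichment score with a gene-set permutation null
#'
#' Draws `n_perm` random gene sets of the same effective size from the
#' ranked universe (without replacement), computes their enrichment
#' scores, and normalizes the observed ES by the mean of the null scores
#' that share its sign (the pre-ranked GSEA convention).  The nominal p is
#' the fraction of same-sign null scores at least as extreme as the
#' observed one, with a +1 pseudocount on numerator and denominator.
#'
#' @inheritParams prerank_es
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation draws; identical seeds
#'   give bit-identical results.
#' @param null_positions optional pre-drawn position matrix (k x n_perm),
#'   as produced internally; used by [screen_perturbations()] to share
#'   draws across experiments.  Results are identical to drawing under
#'   `seed` directly.
#' @param keep_null also return the vector of null enrichment scores.
#' @return an `enrichment_result`: list with `es`, `nes`, `nominal_p`,
#'   `n_perm`, `set_size_used` (and `null_es` when `keep_null = TRUE`).
#' @export
prerank_nes <- function(ranked, gene_set, n_perm = 1000, seed = NULL,
                        weight = 1, null_positions = NULL,
                        keep_null = FALSE) {
  ranked <- as_ranked_list(ranked)
  genes <- names(ranked)
  N <- length(genes)
  pos <- which(genes %in% .as_genes(gene_set))
  k <- length(pos)
  if (k == 0L) stop("gene set does not intersect the ranked list")
  if (k == N) stop("gene set covers the entire ranked list")
  aw <- abs(unclass(ranked))^weight
  es <- .es_core(pos, aw, N)

  if (is.null(null_positions)) {
    if (n_perm < 100L) stop("n_perm must be at least 100")
    null_positions <- .draw_null_positions(N, k, n_perm, seed)
  } else {
    if (nrow(null_positions) != k) {
      stop("null_positions has ", nrow(null_positions),
           " rows but the effective set size is ", k)
    }
  }
  null_es <- vapply(seq_len(ncol(null_positions)),
                    function(b) .es_core(null_positions[, b], aw, N),
                    numeric(1))

  if (es == 0) {
    nes <- 0
    p <- 1
  } else {
    same <- null_es != 0 & sign(null_es) == sign(es)
    if (!any(same)) {
      stop("no permutation enrichment scores share the sign of ES = ",
           signif(es, 4), " (set size ", k, "); NES undefined")
    }
    nes <- es / abs(mean(null_es[same]))
    p <- (1 + sum(abs(null_es[same]) >= abs(es))) / (1 + sum(same))
  }
  out <- list(es = es, nes = nes, nominal_p = p,
              n_perm = ncol(null_positions), set_size_used = k)
  if (keep_null) out$null_es <- null_es
  structure(out, class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("ES = %.4f, NES = %.4f, p = %.4g (set size %d, %d permutations)\n",
              x$es, x$nes, x$nominal_p, x$set_size_used, x$n_perm))
  invisible(x)
}

#' RS score: sensitivity-minus-resistance enrichment
#'
#' The RS score of a ranked profile is the enrichment of the sensitivity
#' (S) signature minus the enrichment of the resistance (R) signature,
#' using either the raw enrichment score (default, used for per-patient
#' response scoring) or the permutation-normalized NES.
#'
#' @inheritParams prerank_nes
#' @param sig_R,sig_S resistance and sensitivity gene sets.
#' @param use_nes use NES instead of ES.
#' @return scalar RS score; positive values mean the profile looks
#'   anti-PD-1 sensitive.
#' @export
rs_score <- function(ranked, sig_R, sig_S, use_nes = FALSE, n_perm = 1000,
                     seed = NULL, weight = 1) {
  ranked <- as_ranked_list(ranked)
  if (use_nes) {
    s <- prerank_nes(ranked, sig_S, n_perm = n_perm, seed = seed,
                     weight = weight)$nes
    r <- prerank_nes(ranked, sig_R, n_perm = n_perm, seed = seed,
                     weight = weight)$nes
  } else {
    s <- prerank_es(ranked, sig_S, weight = weight)
    r <- prerank_es(ranked, sig_R, weight = weight)
  }
  s - r
}
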