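# Mechanism clustering of R-to-S shifting compounds: per-compound
# consensus expression-change signatures, Ward clustering on correlation
# distance, median cluster signatures and pre-ranked enrichment
# annotation.

#' Consensus expression-change signature of one compound
#'
#' Maps each experiment's differential value onto a ternary indicator
#' (+1 when the value is strictly greater than 1, -1 when strictly less
#' than -1, 0 otherwise; exactly +/-1 maps to 0) and sums the indicators
#' per gene across the compound's experiments.
#'
#' @param profiles numeric matrix (genes x experiments) of the compound's
#'   differential profiles; a named vector is treated as one experiment.
#' @return named integer-valued vector with attribute `n_experiments`.
#' @export
consensus_signature <- function(profiles) {
  if (is.vector(profiles)) {
    profiles <- matrix(profiles, ncol = 1L,
                       dimnames = list(names(profiles), "exp1"))
  }
  if (!is.numeric(profiles) || is.null(rownames(profiles))) {
    stop("profiles must be a numeric matrix with gene row names")
  }
  if (ncol(profiles) < 1L) stop("need at least 1 experiment column")
  ind <- (profiles > 1) - (profiles < -1)
  out <- rowSums(ind)
  attr(out, "n_experiments") <- ncol(profiles)
  out
}

#' Cluster compounds by consensus signature
#'
#' Hierarchical Ward clustering of compounds.  The default distance is
#' one minus the Pearson correlation between consensus vectors, combined
#' with the `"ward.D"` Lance-Williams update (which treats the supplied
#' dissimilarity as squared-Euclidean-like; an approximation, since Ward
#' linkage is defined for Euclidean geometry).  `distance = "euclidean"`
#' instead runs exact Ward (`"ward.D2"`) on the raw consensus vectors.
#' The tree is cut at `cut_height`; when that yields a single cluster the
#' cut falls back to k = 2 with a message.
#'
#' @param consensus_matrix numeric matrix, one row per compound
#'   (compound x gene consensus values).
#' @param cut_height dendrogram cut height; default 12.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @return a `mechanism_clusters` object: `labels` (named integer vector,
#'   contiguous from 1), the `hclust` tree, `cut_height`, `distance` and
#'   `excluded` (zero-variance compounds dropped with a warning).
#' @export
cluster_compounds <- function(consensus_matrix, cut_height = 12,
                              distance = c("correlation", "euclidean")) {
  distance <- match.arg(distance)
  if (!is.matrix(consensus_matrix) || is.null(rownames(consensus_matrix))) {
    stop("consensus_matrix must be a matrix with compound row names")
  }
  v <- apply(consensus_matrix, 1L, stats::var)
  excluded <- rownames(consensus_matrix)[v == 0]
  if (length(excluded)) {
    warning("excluded ", length(excluded),
            " compound(s) with zero-variance consensus: ",
            paste(excluded, collapse = ", "), call. = FALSE)
    consensus_matrix <- consensus_matrix[v > 0, , drop = FALSE]
  }
  n <- nrow(consensus_matrix)
  if (n == 0L) stop("no compounds left after zero-variance exclusion")
  if (n == 1L) {
    warning("single compound after exclusions; returning one singleton cluster",
            call. = FALSE)
    return(structure(list(
      labels = stats::setNames(1L, rownames(consensus_matrix)),
      hclust = NULL, cut_height = cut_height, distance = distance,
      excluded = excluded), class = "mechanism_clusters"))
  }
  if (distance == "correlation") {
    d <- stats::as.dist(1 - stats::cor(t(consensus_matrix)))
    hc <- stats::hclust(d, method = "ward.D")
  } else {
    hc <- stats::hclust(stats::dist(consensus_matrix), method = "ward.D2")
  }
  labels <- stats::cutree(hc, h = cut_height)
  if (max(labels) == 1L) {
    message("cluster_compounds: cut at height ", cut_height,
            " yields one cluster; falling back to k = 2")
    labels <- stats::cutree(hc, k = 2L)
  }
  structure(list(labels = labels, hclust = hc, cut_height = cut_height,
                 distance = distance, excluded = excluded),
            class = "mechanism_clusters")
}

#' @export
print.mechanism_clusters <- function(x, ...) {
  cat("Mechanism clustering (Ward, ", x$distance, " distance)\n", sep = "")
  tab <- table(x$labels)
  cat(sprintf("  %d compounds in %d cluster(s): %s\n", length(x$labels),
              length(tab),
              paste(sprintf("#%s n=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  if (length(x$excluded)) {
    cat("  excluded (zero variance):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.mechanism_clusters <- function(x, ...) {
  if (is.null(x$hclust)) stop("nothing to plot for a singleton clustering")
  graphics::plot(x$hclust, xlab = "", sub = "",
                 main = "Compound mechanism dendrogram", ...)
  graphics::abline(h = x$cut_height, lty = 2)
  invisible(x)
}

#' Ranked median consensus signature of a cluster
#'
#' Per gene, the median consensus value across the cluster members (even
#' member counts take the arithmetic midpoint), ranked descending by
#' [rank_genes()].
#'
#' @param members numeric matrix (genes x members) of consensus vectors,
#'   or a list of named consensus vectors sharing the same genes.
#' @return a `ranked_list`.
#' @export
cluster_ranked_signature <- function(members) {
  if (is.list(members) && !is.data.frame(members)) {
    genes <- names(members[[1L]])
    members <- vapply(members, function(m) as.numeric(m[genes]),
                      numeric(length(genes)))
    members <- matrix(members, nrow = length(genes),
                      dimnames = list(genes, NULL))
  }
  if (!is.matrix(members) || is.null(rownames(members))) {
    stop("members must be a genes x members matrix with gene row names")
  }
  if (ncol(members) < 1L) stop("need at least one cluster member")
  med <- apply(members, 1L, stats::median)
  rank_genes(med)
}

#' Annotate a cluster signature against a gene-set collection
#'
#' Runs [prerank_nes()] for every gene set that passes the
#' minimum-overlap rule against the cluster's ranked median signature.
#' Two multiplicity-corrected columns are reported: `fdr_q`, the
#' pre-ranked GSEA false-discovery q-value computed from the permutation
#' null NES pooled across all tested sets (the convention that retains
#' resolution below `1 / n_perm` at a finite permutation count), and
#' `p_adjust_bh`, Benjamini-Hochberg on the per-set nominal p.
#'
#' @param cluster_signature a `ranked_list` (see
#'   [cluster_ranked_signature()]).
#' @param gene_sets named list of gene sets (see [read_gmt()]).
#' @param n_perm permutations per set; default 1000.
#' @param seed integer seed; identical seeds give identical tables.
#' @param weight,min_genes,min_frac see [prerank_nes()] and the overlap
#'   rule.
#' @return data frame sorted by NES descending with columns `set`,
#'   `set_size_used`, `es`, `nes`, `nominal_p`, `p_adjust_bh`, `fdr_q`.
#' @export
annotate_cluster <- function(cluster_signature, gene_sets, n_perm = 1000,
                             seed = 1, weight = 1, min_genes = 15,
                             min_frac = 0.5) {
  if (!length(gene_sets)) stop("gene_sets must be non-empty")
  ranked <- as_ranked_list(cluster_signature)
  universe <- names(ranked)
  N <- length(universe)

  cache <- new.env(parent = emptyenv())
  get_positions <- function(k) {
    key <- as.character(k)
    if (is.null(cache[[key]])) {
      cache[[key]] <- .draw_null_positions(N, k, n_perm, seed)
    }
    cache[[key]]
  }

  keep <- vapply(gene_sets, function(g) {
    ov <- .signature_overlap(universe, g, min_genes, min_frac)
    ov$ok && ov$n_overlap < N
  }, logical(1))
  if (!any(keep)) stop("no gene set passes the minimum-overlap rule")
  skipped <- sum(!keep)
  if (skipped) {
    message("annotate_cluster: ", skipped, " set(s) failed the overlap rule")
  }
  gene_sets <- gene_sets[keep]

  res <- lapply(names(gene_sets), function(nm) {
    k <- sum(.as_genes(gene_sets[[nm]]) %in% universe)
    er <- prerank_nes(ranked, gene_sets[[nm]], n_perm = n_perm, seed = seed,
                      weight = weight, null_positions = get_positions(k),
                      keep_null = TRUE)
    list(set = nm, er = er)
  })

  # pooled permutation null NES: each null ES normalized by the mean of
  # its own sign class within its set, mirroring the observed NES.
  null_nes <- unlist(lapply(res, function(x) {
    ne <- x$er$null_es
    pos <- ne[ne > 0]
    neg <- ne[ne < 0]
    c(if (length(pos)) pos / mean(pos),
      if (length(neg)) neg / abs(mean(neg)))
  }), use.names = FALSE)

  tab <- data.frame(
    set = vapply(res, `[[`, character(1), "set"),
    set_size_used = vapply(res, function(x) x$er$set_size_used, integer(1)),
    es = vapply(res, function(x) x$er$es, numeric(1)),
    nes = vapply(res, function(x) x$er$nes, numeric(1)),
    nominal_p = vapply(res, function(x) x$er$nominal_p, numeric(1)),
    stringsAsFactors = FALSE)
  tab$p_adjust_bh <- stats::p.adjust(tab$nominal_p, method = "BH")

  q_of <- function(nes) {
    if (nes > 0) {
      null_side <- null_nes[null_nes > 0]
      obs_side <- tab$nes[tab$nes > 0]
      num <- (1 + sum(null_side >= nes)) / (1 + length(null_side))
      den <- sum(obs_side >= nes) / length(obs_side)
    } else if (nes < 0) {
      null_side <- null_nes[null_nes < 0]
      obs_side <- tab$nes[tab$nes < 0]
      num <- (1 + sum(null_side <= nes)) / (1 + length(null_side))
      den <- sum(obs_side <= nes) / length(obs_side)
    } else {
      return(1)
    }
    min(1, num / den)
  }
  tab$fdr_q <- vapply(tab$nes, q_of, numeric(1))
  # monotonize within each sign class: a weaker NES never gets a smaller q
  for (sgn in c(1, -1)) {
    side <- which(sign(tab$nes) == sgn)
    if (length(side) > 1L) {
      ord <- side[order(-sgn * tab$nes[side])]
      tab$fdr_q[ord] <- cummax(tab$fdr_q[ord])
    }
  }
  tab <- tab[order(-tab$nes), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
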