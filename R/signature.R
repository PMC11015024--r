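# Bootstrapped differential-expression feature selection and the
# cross-validated construction of the resistance (R) and sensitivity (S)
# signatures.  cross_validate_signatures() is the fitting function; it
# returns a classed object with print/summary/coef/predict/plot methods.

# Vectorized two-sample t test across rows; returns p-values and the
# mean difference (group 1 minus group 2).  Rows with zero pooled
# variance get p = NA (treated as non-hits downstream).
.row_ttest <- function(mat, idx1, idx2, welch = FALSE) {
  x1 <- mat[, idx1, drop = FALSE]
  x2 <- mat[, idx2, drop = FALSE]
  n1 <- length(idx1)
  n2 <- length(idx2)
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  if (welch) {
    v1 <- ss1 / (n1 - 1)
    v2 <- ss2 / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  } else {
    sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  tt <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)
  p[se2 == 0] <- NA_real_
  list(p = unname(p), diff = unname(m1 - m2))
}

#' Bootstrapped differential-expression gene selection
#'
#' Runs `n_boot` stratified bootstrap resamples of the cohort (each
#' response stratum resampled with replacement to its own original size).
#' In each resample a two-sided Student's t test (equal variance by
#' default) compares the treatment-induced changes between non-responders
#' and responders, gene by gene.  A gene with `p < alpha` is a hit for
#' that resample: a resistance (R) hit when its mean change is higher in
#' non-responders, a sensitivity (S) hit when higher in responders.  The
#' per-gene hit fraction over the `n_boot` resamples is the DEG selection
#' score for each direction; a gene is R- or S-hit in any one resample,
#' never both, so the two fractions sum to at most 1.
#'
#' A resample whose stratum collapses onto fewer than 2 distinct patients
#' is redrawn (at most 10 attempts).  Genes with zero pooled variance in
#' a resample are non-hits for that resample.
#'
#' @param delta complete matrix of treatment-induced changes
#'   (genes x patients).
#' @param labels per-patient response labels; both classes need at least
#'   3 patients.
#' @param n_boot number of bootstrap resamples; default 100.
#' @param alpha per-test significance threshold; default 0.05.
#' @param seed integer seed; the procedure is deterministic given it.
#' @param variance `"equal"` for Student's t (default) or `"welch"`.
#' @return a `deg_selection` data frame with columns `gene`,
#'   `hit_fraction_R`, `hit_fraction_S` and attributes `n_boot`, `alpha`.
#' @export
bootstrap_deg_selection <- function(delta, labels, n_boot = 100, alpha = 0.05,
                                    seed = NULL,
                                    variance = c("equal", "welch")) {
  variance <- match.arg(variance)
  .check_matrix(delta, "delta matrix")
  if (anyNA(delta)) stop("delta matrix must be complete")
  lab <- .as_response(labels)
  if (length(lab) != ncol(delta)) stop("one label per patient column required")
  if (sum(lab) < 3L || sum(!lab) < 3L) {
    stop("each response class needs at least 3 patients")
  }
  if (!is.null(seed)) set.seed(seed)
  idx_resp <- which(lab)
  idx_non <- which(!lab)

  draw_stratum <- function(idx) {
    for (a in 1:10) {
      d <- sample(idx, length(idx), replace = TRUE)
      if (length(unique(d)) >= 2L) return(d)
    }
    stop("bootstrap stratum collapsed to fewer than 2 distinct patients ",
         "after 10 redraw attempts")
  }

  nR <- integer(nrow(delta))
  nS <- integer(nrow(delta))
  for (t in seq_len(n_boot)) {
    bn <- draw_stratum(idx_non)
    br <- draw_stratum(idx_resp)
    tt <- .row_ttest(delta, bn, br, welch = variance == "welch")
    hit <- !is.na(tt$p) & tt$p < alpha
    nR <- nR + (hit & tt$diff > 0)   # higher in non-responders
    nS <- nS + (hit & tt$diff < 0)   # higher in responders
  }
  structure(
    data.frame(gene = rownames(delta),
               hit_fraction_R = nR / n_boot,
               hit_fraction_S = nS / n_boot,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("deg_selection", "data.frame"),
    n_boot = n_boot, alpha = alpha)
}

.gene_signature <- function(name, direction, genes, selection_percent) {
  structure(list(name = name, direction = direction,
                 genes = unique(as.character(genes)),
                 selection_percent = selection_percent),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("%s signature '%s': %d genes (top %g%% of selection scores)\n",
              x$direction, x$name, length(x$genes), x$selection_percent))
  invisible(x)
}

# Top pct% of genes with positive selection fraction; boundary ties all
# included, count is ceiling(n_positive * pct / 100).
.top_percent <- function(frac, pct) {
  pos <- frac[frac > 0]
  if (!length(pos)) return(character(0))
  n_top <- ceiling(length(pos) * pct / 100)
  ord <- order(-pos, names(pos), method = "radix")
  thr <- pos[ord][n_top]
  names(pos)[pos >= thr]
}

#' Candidate R/S signatures from DEG selection scores
#'
#' The candidate resistance signature `R_i` contains the genes whose
#' R-direction hit fraction falls in the top `i` percent of genes with a
#' positive R fraction (count `ceiling(n * i / 100)`, with boundary ties
#' all included); `S_j` symmetrically for the S direction.
#'
#' @param scores a `deg_selection` result.
#' @param i,j selection percentages for the R and S directions.
#' @return list with `gene_signature` components `R` and `S`.
#' @export
candidate_signatures <- function(scores, i, j) {
  if (!inherits(scores, "deg_selection")) {
    stop("scores must come from bootstrap_deg_selection()")
  }
  fr <- stats::setNames(scores$hit_fraction_R, scores$gene)
  fs <- stats::setNames(scores$hit_fraction_S, scores$gene)
  gR <- .top_percent(fr, i)
  gS <- .top_percent(fs, j)
  if (!length(gR)) stop("no genes with positive R hit fraction; empty signature")
  if (!length(gS)) stop("no genes with positive S hit fraction; empty signature")
  list(R = .gene_signature(sprintf("R_%g", i), "R", gR, i),
       S = .gene_signature(sprintf("S_%g", j), "S", gS, j))
}

#' Fit R/S response signatures by cross-validated bootstrap selection
#'
#' The signature-construction procedure: a stratified leave-out split is
#' held back, the remaining patients undergo stratified k-fold
#' cross-validation, and within each training fold
#' [bootstrap_deg_selection()] produces DEG selection scores from which
#' candidate signatures `(R_i, S_j)` are formed over a grid of selection
#' percentages.  Each grid point is scored by the mean AUC, over folds, of
#' the per-patient RS score (enrichment of `S_j` minus enrichment of
#' `R_i` in the patient's ranked expression changes) against the response
#' labels.  Core signatures at a grid point are the genes shared by the
#' fold candidates of all folds (falling back to genes shared by all but
#' one fold, with a warning, when the full intersection is empty); the
#' leave-out AUC is computed with the core signatures on the held-out
#' patients.
#'
#' The chosen `(i, j)` maximizes the mean of cross-validation and
#' leave-out AUC among grid points whose core signatures are
#' size-balanced (smaller/larger >= 0.5); ties prefer smaller signatures.
#' The whole procedure is a pure function of the data, the grid and the
#' seed.
#'
#' @inheritParams bootstrap_deg_selection
#' @param grid data frame with columns `i` and `j` (selection
#'   percentages); default all combinations of 5, 10, ..., 50.
#' @param n_folds number of cross-validation folds; default 3.
#' @param leaveout_fraction fraction of each class held out for the final
#'   validation split; default 0.25.
#' @param weight GSEA weighting exponent used in the RS scores.
#' @return an object of class `rs_signature` with the evaluated `grid`,
#'   chosen `i`/`j`, per-fold candidates, core signatures `core_R` and
#'   `core_S`, and `cv_auc` / `leaveout_auc` at the chosen point.
#' @seealso [evaluate_signature()], [predict.rs_signature()]
#' @export
cross_validate_signatures <- function(delta, labels, grid = NULL, n_folds = 3,
                                      leaveout_fraction = 0.25, n_boot = 100,
                                      alpha = 0.05, seed = 1, weight = 1,
                                      variance = c("equal", "welch")) {
  variance <- match.arg(variance)
  .check_matrix(delta, "delta matrix")
  if (anyNA(delta)) stop("delta matrix must be complete")
  lab <- .as_response(labels)
  if (length(lab) != ncol(delta)) stop("one label per patient column required")
  names(lab) <- colnames(delta)
  if (is.null(grid)) grid <- expand.grid(i = seq(5, 50, by = 5),
                                         j = seq(5, 50, by = 5))
  if (!all(c("i", "j") %in% names(grid))) stop("grid needs columns i and j")

  set.seed(seed)
  idx_resp <- which(lab)
  idx_non <- which(!lab)
  lo <- c(sample(idx_resp, round(length(idx_resp) * leaveout_fraction)),
          sample(idx_non, round(length(idx_non) * leaveout_fraction)))
  pool_resp <- setdiff(idx_resp, lo)
  pool_non <- setdiff(idx_non, lo)
  if (length(pool_resp) < 2L * n_folds || length(pool_non) < 2L * n_folds) {
    stop("not enough patients for stratified ", n_folds,
         "-fold cross-validation (need >= 2 per class per fold)")
  }
  foldid <- integer(ncol(delta))
  foldid[pool_resp] <- sample(rep_len(seq_len(n_folds), length(pool_resp)))
  foldid[pool_non] <- sample(rep_len(seq_len(n_folds), length(pool_non)))

  ranked <- lapply(seq_len(ncol(delta)), function(p) rank_genes(delta[, p]))

  is_u <- sort(unique(grid$i))
  js_u <- sort(unique(grid$j))
  fold_scores <- vector("list", n_folds)
  sigsR <- vector("list", n_folds)   # fold -> i -> genes
  sigsS <- vector("list", n_folds)
  esR_cv <- vector("list", n_folds)  # fold -> matrix test-patient x i
  esS_cv <- vector("list", n_folds)
  test_sets <- vector("list", n_folds)

  for (f in seq_len(n_folds)) {
    te <- which(foldid == f)
    tr <- c(pool_resp, pool_non)
    tr <- tr[foldid[tr] != f]
    sc <- bootstrap_deg_selection(delta[, tr, drop = FALSE], lab[tr],
                                  n_boot = n_boot, alpha = alpha,
                                  seed = seed + f, variance = variance)
    fold_scores[[f]] <- sc
    fr <- stats::setNames(sc$hit_fraction_R, sc$gene)
    fs <- stats::setNames(sc$hit_fraction_S, sc$gene)
    sigsR[[f]] <- lapply(stats::setNames(is_u, is_u),
                         function(i) .top_percent(fr, i))
    sigsS[[f]] <- lapply(stats::setNames(js_u, js_u),
                         function(j) .top_percent(fs, j))
    es_fold <- function(genes) {
      if (!length(genes)) return(rep(NA_real_, length(te)))
      vapply(te, function(p) prerank_es(ranked[[p]], genes, weight = weight),
             numeric(1))
    }
    esR_cv[[f]] <- vapply(sigsR[[f]], es_fold, numeric(length(te)))
    esS_cv[[f]] <- vapply(sigsS[[f]], es_fold, numeric(length(te)))
    esR_cv[[f]] <- matrix(esR_cv[[f]], nrow = length(te),
                          dimnames = list(NULL, is_u))
    esS_cv[[f]] <- matrix(esS_cv[[f]], nrow = length(te),
                          dimnames = list(NULL, js_u))
    test_sets[[f]] <- te
  }

  # core signatures per selection percentage: genes shared by all folds,
  # falling back to all-but-one-fold membership when the intersection is
  # empty.
  core_of <- function(sig_lists, key) {
    memb <- table(unlist(lapply(sig_lists, `[[`, key)))
    full <- names(memb)[memb == n_folds]
    if (length(full)) return(list(genes = sort(full), fallback = FALSE))
    list(genes = sort(names(memb)[memb >= n_folds - 1L]), fallback = TRUE)
  }
  coreR <- lapply(stats::setNames(as.character(is_u), is_u),
                  function(k) core_of(sigsR, k))
  coreS <- lapply(stats::setNames(as.character(js_u), js_u),
                  function(k) core_of(sigsS, k))

  es_lo <- function(core_list) {
    vapply(core_list, function(cc) {
      if (!length(cc$genes)) return(rep(NA_real_, length(lo)))
      vapply(lo, function(p) prerank_es(ranked[[p]], cc$genes, weight = weight),
             numeric(1))
    }, numeric(length(lo)))
  }
  esR_lo <- matrix(es_lo(coreR), nrow = length(lo), dimnames = list(NULL, is_u))
  esS_lo <- matrix(es_lo(coreS), nrow = length(lo), dimnames = list(NULL, js_u))

  g <- data.frame(i = grid$i, j = grid$j)
  g$cv_auc <- vapply(seq_len(nrow(g)), function(r) {
    ic <- as.character(g$i[r]); jc <- as.character(g$j[r])
    mean(vapply(seq_len(n_folds), function(f) {
      sc <- esS_cv[[f]][, jc] - esR_cv[[f]][, ic]
      if (anyNA(sc)) return(NA_real_)
      roc_auc(lab[test_sets[[f]]], sc)
    }, numeric(1)))
  }, numeric(1))
  g$n_core_R <- vapply(as.character(g$i), function(k) length(coreR[[k]]$genes),
                       integer(1))
  g$n_core_S <- vapply(as.character(g$j), function(k) length(coreS[[k]]$genes),
                       integer(1))
  g$core_fallback <- vapply(seq_len(nrow(g)), function(r) {
    coreR[[as.character(g$i[r])]]$fallback ||
      coreS[[as.character(g$j[r])]]$fallback
  }, logical(1))
  g$leaveout_auc <- vapply(seq_len(nrow(g)), function(r) {
    sc <- esS_lo[, as.character(g$j[r])] - esR_lo[, as.character(g$i[r])]
    if (anyNA(sc)) return(NA_real_)
    roc_auc(lab[lo], sc)
  }, numeric(1))
  g$balanced <- pmin(g$n_core_R, g$n_core_S) /
    pmax(g$n_core_R, g$n_core_S) >= 0.5
  g$balanced[g$n_core_R == 0L | g$n_core_S == 0L] <- FALSE
  g$objective <- (g$cv_auc + g$leaveout_auc) / 2

  eligible <- g$balanced & is.finite(g$objective)
  if (!any(eligible)) {
    warning("no grid point satisfies the size-balance constraint; ",
            "choosing among all grid points", call. = FALSE)
    eligible <- is.finite(g$objective)
    if (!any(eligible)) stop("no usable grid point (all core signatures empty)")
  }
  cand <- which(eligible)
  best <- cand[order(-g$objective[cand],
                     g$n_core_R[cand] + g$n_core_S[cand],
                     cand)][1L]
  if (g$core_fallback[best]) {
    warning("empty core intersection at the chosen grid point; using genes ",
            "shared by at least ", n_folds - 1L, " of ", n_folds, " folds",
            call. = FALSE)
  }
  ch_i <- g$i[best]
  ch_j <- g$j[best]

  structure(list(
    grid = g,
    chosen_i = ch_i,
    chosen_j = ch_j,
    core_R = .gene_signature("core_R", "R",
                             coreR[[as.character(ch_i)]]$genes, ch_i),
    core_S = .gene_signature("core_S", "S",
                             coreS[[as.character(ch_j)]]$genes, ch_j),
    cv_auc = g$cv_auc[best],
    leaveout_auc = g$leaveout_auc[best],
    core_fallback = g$core_fallback[best],
    fold_candidates = lapply(seq_len(n_folds), function(f) {
      list(R = sigsR[[f]][[as.character(ch_i)]],
           S = sigsS[[f]][[as.character(ch_j)]])
    }),
    fold_scores = fold_scores,
    leaveout_patients = colnames(delta)[lo],
    n_folds = n_folds, n_boot = n_boot, alpha = alpha, seed = seed,
    weight = weight,
    call = match.call()
  ), class = "rs_signature")
}

#' @export
print.rs_signature <- function(x, ...) {
  cat("Cross-validated anti-PD-1 response signatures\n")
  cat(sprintf("  chosen selection percentages: i = %g (R), j = %g (S)\n",
              x$chosen_i, x$chosen_j))
  cat(sprintf("  core signatures: %d R genes, %d S genes%s\n",
              length(x$core_R$genes), length(x$core_S$genes),
              if (x$core_fallback) " (fallback core)" else ""))
  cat(sprintf("  cross-validation AUC = %.3f, leave-out AUC = %.3f\n",
              x$cv_auc, x$leaveout_auc))
  invisible(x)
}

#' @export
summary.rs_signature <- function(object, n_top = 5, ...) {
  print(object)
  g <- object$grid
  g <- g[order(-g$objective), ]
  cat("\nTop grid points by objective (mean of CV and leave-out AUC):\n")
  print(utils::head(g[, c("i", "j", "cv_auc", "leaveout_auc",
                          "n_core_R", "n_core_S", "balanced")], n_top),
        row.names = FALSE)
  invisible(g)
}

#' Extract the fitted core signatures
#'
#' @param object an `rs_signature` fit.
#' @param ... unused.
#' @return list with character vectors `R` and `S`.
#' @export
coef.rs_signature <- function(object, ...) {
  list(R = object$core_R$genes, S = object$core_S$genes)
}

#' Score new patients with fitted signatures
#'
#' Computes the RS score (enrichment of the core S signature minus
#' enrichment of the core R signature) for each column of a new delta
#' matrix, optionally thresholding it into predicted response classes.
#'
#' @param object an `rs_signature` fit.
#' @param newdata matrix of treatment-induced changes (genes x patients).
#' @param type `"score"` for RS scores, `"class"` for
#'   responder/non-responder calls at `threshold`.
#' @param threshold RS-score cut for `type = "class"`; default 0.
#' @param use_nes,n_perm,seed passed to [rs_score()].
#' @param ... unused.
#' @return named numeric scores or character class labels.
#' @export
predict.rs_signature <- function(object, newdata, type = c("score", "class"),
                                 threshold = 0, use_nes = FALSE,
                                 n_perm = 1000, seed = NULL, ...) {
  type <- match.arg(type)
  .check_matrix(newdata, "newdata")
  scores <- vapply(seq_len(ncol(newdata)), function(p) {
    rs_score(rank_genes(newdata[, p]), object$core_R$genes,
             object$core_S$genes, use_nes = use_nes, n_perm = n_perm,
             seed = seed, weight = object$weight)
  }, numeric(1))
  names(scores) <- colnames(newdata)
  if (type == "score") return(scores)
  ifelse(scores > threshold, "responder", "non-responder")
}

#' Heatmap of the cross-validation AUC grid
#'
#' @param x an `rs_signature` fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.rs_signature <- function(x, ...) {
  g <- x$grid
  is_u <- sort(unique(g$i))
  js_u <- sort(unique(g$j))
  z <- matrix(NA_real_, length(is_u), length(js_u))
  z[cbind(match(g$i, is_u), match(g$j, js_u))] <- g$cv_auc
  graphics::image(is_u, js_u, z, xlab = "i (% of R hits)",
                  ylab = "j (% of S hits)",
                  main = "Cross-validation AUC", ...)
  graphics::points(x$chosen_i, x$chosen_j, pch = 4, cex = 2, lwd = 2)
  invisible(x)
}

#' Evaluate fixed R/S signatures on a cohort
#'
#' Scores every patient column of `delta` with the RS score of the given
#' signatures and returns the AUC against the response labels.  Each
#' signature must retain at least `min_genes` members and `min_frac` of
#' its members inside the cohort gene universe.
#'
#' @inheritParams cross_validate_signatures
#' @param sig_R,sig_S resistance and sensitivity gene sets (character
#'   vectors or `gene_signature` objects).
#' @param use_nes,n_perm score with NES instead of ES.
#' @param min_genes,min_frac minimum-overlap rule.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_signature <- function(delta, labels, sig_R, sig_S, use_nes = FALSE,
                               n_perm = 1000, seed = NULL, weight = 1,
                               min_genes = 15, min_frac = 0.5) {
  .check_matrix(delta, "delta matrix")
  lab <- .as_response(labels)
  universe <- rownames(delta)
  for (sig in list(R = sig_R, S = sig_S)) {
    ov <- .signature_overlap(universe, sig, min_genes, min_frac)
    if (!ov$ok) {
      stop("insufficient overlap: signature retains ", ov$n_overlap, " of ",
           ov$n_set, " genes in the cohort universe")
    }
  }
  scores <- vapply(seq_len(ncol(delta)), function(p) {
    rs_score(rank_genes(delta[, p]), sig_R, sig_S, use_nes = use_nes,
             n_perm = n_perm, seed = seed, weight = weight)
  }, numeric(1))
  roc_auc(lab, scores)
}
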