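# PCA response score, ROC AUC and correlation-based association helpers.

#' First-principal-component response score
#'
#' Projects patients onto the first principal component of the
#' patient-by-gene matrix (genes centred and scaled to unit variance;
#' zero-variance genes dropped with a message).  The sign of a principal
#' component is arbitrary, so when labels are supplied the score is
#' oriented to give AUC >= 0.5 against them; otherwise the loading of the
#' lexicographically first gene is made non-negative, so the result is
#' deterministic either way.
#'
#' @param delta matrix of expression changes (genes x patients).
#' @param labels optional per-patient response labels used only to orient
#'   the score.
#' @return named numeric score per patient.
#' @export
pca_response_score <- function(delta, labels = NULL) {
  .check_matrix(delta)
  if (ncol(delta) < 2L) stop("need at least 2 patients")
  v <- apply(delta, 1L, stats::var)
  keep <- v > 0
  if (sum(keep) < 2L) stop("need at least 2 genes with nonzero variance")
  if (any(!keep)) {
    message("pca_response_score: dropped ", sum(!keep), " zero-variance gene(s)")
  }
  x <- t(delta[keep, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  s <- pc$x[, 1L]
  flip <- FALSE
  if (!is.null(labels)) {
    lab <- .as_response(labels)
    .check_both_classes(lab)
    if (roc_auc(lab, s) < 0.5) flip <- TRUE
  } else {
    first_gene <- sort(colnames(x), method = "radix")[1L]
    if (pc$rotation[first_gene, 1L] < 0) flip <- TRUE
  }
  if (flip) s <- -s
  names(s) <- colnames(delta)
  s
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of `scores` against binary labels;
#' tied scores contribute 1/2.
#'
#' @param labels binary response labels (responder = positive class).
#' @param scores numeric classification scores, higher = more
#'   responder-like.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  lab <- .as_response(labels)
  .check_both_classes(lab)
  if (length(lab) != length(scores)) stop("labels and scores lengths differ")
  if (anyNA(scores)) stop("scores contain missing values")
  r <- rank(scores)
  n1 <- sum(lab)
  n0 <- sum(!lab)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Correlation between a signature readout and an immunity covariate
#'
#' Two-sided Pearson or Spearman correlation test; numerical p-value
#' underflow is reported as `1e-300` rather than 0.
#'
#' @param x,y numeric vectors of equal length (>= 3), finite values.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with components `r` and `p`.
#' @export
immunity_association <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = max(ct$p.value, 1e-300))
}
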