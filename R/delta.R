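# Treatment-induced expression changes: the paired log2 fold change and
# the population-baseline surrogate for unpaired cohorts.

#' Log2-transform raw counts
#'
#' Convenience preprocessing for cohorts supplied as raw counts; the
#' pipeline itself expects log2-scale input.  Pseudocount 1 keeps zeros at
#' zero.
#'
#' @param x numeric matrix or vector of non-negative counts.
#' @return `log2(x + 1)` with a `log2_expression` value-kind attribute.
#' @export
log2_normalize <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("counts must be non-negative")
  .set_value_kind(log2(x + 1), "log2_expression")
}

#' Per-patient treatment-induced expression changes
#'
#' The treatment-induced change of a gene is the log2 fold change between
#' on-treatment and pre-treatment expression of the same patient, i.e. the
#' difference of the two log2-scale matrices.
#'
#' @param cohort a [paired_cohort()].
#' @return matrix of changes (genes x patients) with attributes
#'   `value_kind = "delta_log2fc"` and `provenance = "paired"`.
#' @export
treatment_induced_changes <- function(cohort) {
  if (!inherits(cohort, "paired_cohort")) stop("cohort must be a paired_cohort")
  for (m in list(cohort$pre, cohort$post)) {
    vk <- .value_kind(m)
    if (!is.null(vk) && vk != "log2_expression") {
      stop("treatment_induced_changes expects log2_expression input, got ", vk)
    }
  }
  d <- cohort$post - cohort$pre
  d <- .set_value_kind(d, "delta_log2fc")
  attr(d, "provenance") <- "paired"
  d
}

#' Baseline-relative expression changes for unpaired cohorts
#'
#' For cohorts without matched pre/on-treatment samples, the relative
#' expression of each gene with respect to the cohort population baseline
#' serves as a surrogate for the treatment-induced change: each row is
#' centred on its cohort-wide mean (or median).
#'
#' @param expr numeric matrix (genes x samples), at least 2 samples.
#' @param center baseline statistic, `"mean"` (default) or `"median"`.
#' @return centred matrix with `value_kind = "delta_log2fc"` and
#'   `provenance = "baseline_surrogate"`.
#' @export
baseline_relative_changes <- function(expr, center = c("mean", "median")) {
  center <- match.arg(center)
  .check_matrix(expr)
  if (ncol(expr) < 2L) {
    stop("baseline_relative_changes needs at least 2 samples")
  }
  base <- if (center == "mean") rowMeans(expr) else apply(expr, 1L, stats::median)
  d <- expr - base
  d <- .set_value_kind(d, "delta_log2fc")
  attr(d, "provenance") <- "baseline_surrogate"
  d
}
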