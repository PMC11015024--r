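# Paired pre/on-treatment cohorts: construction, biopsy merging and the
# perturbation-matrix preprocessing filters.

#' Construct a paired pre/on-treatment cohort
#'
#' Container for a matched pair of log2-scale expression matrices with one
#' column per patient and a known binary anti-PD-1 response per patient.
#'
#' @param pre,post numeric matrices (genes x patients) on log2 scale, with
#'   identical row and column names.
#' @param response per-patient labels (`"responder"`/`"non-responder"`,
#'   logical, or 0/1), named by patient or in column order.
#' @return an object of class `paired_cohort` with components `pre`,
#'   `post`, `patients` and `response`.
#' @export
paired_cohort <- function(pre, post, response) {
  .check_matrix(pre, "pre matrix")
  .check_matrix(post, "post matrix")
  if (!identical(rownames(pre), rownames(post))) {
    stop("pre and post matrices must share identical gene ids")
  }
  if (!identical(colnames(pre), colnames(post))) {
    stop("pre and post matrices must share identical, patient-aligned columns")
  }
  if (anyNA(pre) || anyNA(post)) stop("expression matrices contain missing values")
  lab <- .as_response(response)
  if (length(lab) != ncol(pre)) {
    stop("response must have one label per patient column")
  }
  if (!is.null(names(lab))) {
    if (!setequal(names(lab), colnames(pre))) {
      stop("response names do not match patient columns")
    }
    lab <- lab[colnames(pre)]
  } else {
    names(lab) <- colnames(pre)
  }
  structure(list(
    pre = .set_value_kind(pre, "log2_expression"),
    post = .set_value_kind(post, "log2_expression"),
    patients = colnames(pre),
    response = ifelse(lab, "responder", "non-responder")
  ), class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  lab <- .as_response(x$response)
  cat("Paired pre/on-treatment cohort\n")
  cat(sprintf("  %d patients (%d responders / %d non-responders), %d genes\n",
              length(x$patients), sum(lab), sum(!lab), nrow(x$pre)))
  invisible(x)
}

#' Average multiple biopsies into one column per patient-timepoint
#'
#' @param expr numeric matrix (genes x samples).
#' @param sample_to_patient named character vector mapping every sample id
#'   to its patient-timepoint group; singleton groups pass through.
#' @return matrix with one column per group (gene-wise arithmetic mean),
#'   columns ordered by sorted group id.
#' @export
merge_biopsies <- function(expr, sample_to_patient) {
  .check_matrix(expr)
  if (is.null(names(sample_to_patient)) ||
      !all(colnames(expr) %in% names(sample_to_patient))) {
    stop("sample_to_patient must map every sample id of expr")
  }
  grp <- as.character(sample_to_patient[colnames(expr)])
  groups <- sort(unique(grp))
  out <- vapply(groups, function(g) {
    rowMeans(expr[, grp == g, drop = FALSE])
  }, numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr), dimnames = list(rownames(expr), groups))
  if (!is.null(.value_kind(expr))) out <- .set_value_kind(out, .value_kind(expr))
  out
}

#' Read a paired cohort from expression and clinical tables
#'
#' The clinical table (TSV) must contain columns `sample_id`,
#' `patient_id`, `timepoint` (`pre`/`post`) and `response`
#' (`responder`/`non-responder`/`unknown`).  Patients with response
#' `unknown` or with a missing timepoint are dropped with a message.
#' Multiple biopsies of the same patient-timepoint are an error unless
#' `merge_multiple_biopsies = TRUE`, in which case they are averaged.
#'
#' @param expr_path path to a TSV expression table (first column gene ids,
#'   remaining columns samples, log2 scale), or a character vector of two
#'   paths (pre- and on-treatment tables) whose gene lists are intersected
#'   with a message when they differ.
#' @param clinical_path path to the clinical TSV described above.
#' @param merge_multiple_biopsies average multiple biopsies per
#'   patient-timepoint instead of failing.
#' @return a [paired_cohort()], patients sorted by id.
#' @export
read_cohort_tables <- function(expr_path, clinical_path,
                               merge_multiple_biopsies = FALSE) {
  read_tsv_matrix <- function(p) {
    df <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1L]])
    m
  }
  mats <- lapply(expr_path, read_tsv_matrix)
  if (length(mats) == 1L) {
    expr <- mats[[1L]]
  } else {
    common <- Reduce(intersect, lapply(mats, rownames))
    if (!length(common)) stop("expression tables share no genes")
    dropped <- sum(vapply(mats, nrow, integer(1))) - length(common) * length(mats)
    if (dropped > 0L) {
      message("read_cohort_tables: gene lists differ between files; ",
              dropped, " row(s) outside the intersection dropped")
    }
    expr <- do.call(cbind, lapply(mats, function(m) m[common, , drop = FALSE]))
  }
  .check_matrix(expr, "cohort expression matrix")
  incomplete <- apply(expr, 1L, anyNA)
  if (any(incomplete)) {
    message("read_cohort_tables: dropped ", sum(incomplete),
            " gene(s) with missing values")
    expr <- expr[!incomplete, , drop = FALSE]
  }

  clin <- utils::read.delim(clinical_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "timepoint", "response")
  if (!all(need %in% names(clin))) {
    stop("clinical table must contain columns: ", paste(need, collapse = ", "))
  }
  if (!all(clin$timepoint %in% c("pre", "post"))) {
    stop("timepoint must be 'pre' or 'post'")
  }
  if (!all(clin$response %in% c("responder", "non-responder", "unknown"))) {
    stop("response must be responder/non-responder/unknown")
  }
  clin <- clin[clin$sample_id %in% colnames(expr), , drop = FALSE]

  unk <- unique(clin$patient_id[clin$response == "unknown"])
  if (length(unk)) {
    message("read_cohort_tables: excluded ", length(unk),
            " patient(s) with unknown response")
    clin <- clin[!clin$patient_id %in% unk, , drop = FALSE]
  }

  key <- paste(clin$patient_id, clin$timepoint, sep = "||")
  if (anyDuplicated(key)) {
    if (!merge_multiple_biopsies) {
      dup <- key[duplicated(key)][1L]
      stop("patient has multiple samples for one timepoint (",
           sub("\\|\\|", " / ", dup),
           "); set merge_multiple_biopsies = TRUE to average them")
    }
    expr <- merge_biopsies(expr[, clin$sample_id, drop = FALSE],
                           stats::setNames(key, clin$sample_id))
    clin <- clin[!duplicated(key), , drop = FALSE]
    clin$sample_id <- key[!duplicated(key)]
  }

  tab <- table(clin$patient_id, clin$timepoint)
  complete <- rownames(tab)[tab[, "pre", drop = TRUE] >= 1 &
                            tab[, "post", drop = TRUE] >= 1]
  n_excl <- length(unique(clin$patient_id)) - length(complete)
  if (n_excl > 0L) {
    message("read_cohort_tables: excluded ", n_excl,
            " patient(s) lacking a pre or post sample")
  }
  if (!length(complete)) stop("no patients with both timepoints and known response")
  complete <- sort(complete)

  pick <- function(tp) {
    ids <- vapply(complete, function(p) {
      clin$sample_id[clin$patient_id == p & clin$timepoint == tp][1L]
    }, character(1))
    m <- expr[, ids, drop = FALSE]
    colnames(m) <- complete
    m
  }
  response <- vapply(complete, function(p) {
    clin$response[clin$patient_id == p][1L]
  }, character(1))
  paired_cohort(pick("pre"), pick("post"), response)
}

#' Apply transcriptional-activity and gene-space filters to a perturbation matrix
#'
#' Experiments with a transcriptional activity score (TAS) below `min_tas`
#' are removed (the threshold is inclusive: TAS equal to `min_tas` is
#' kept), and rows are restricted to the requested gene space, preserving
#' the order of `gene_space`.
#'
#' @param mat numeric matrix (genes x experiments).
#' @param metadata data frame with `experiment_id` matching the columns of
#'   `mat` and a numeric `tas` column in `[0, 1]`.
#' @param min_tas minimum transcriptional activity score; default 0.4.
#' @param gene_space character vector of gene ids to retain.
#' @return list with filtered `matrix` and `metadata`.
#' @export
filter_perturbations <- function(mat, metadata, min_tas = 0.4, gene_space) {
  .check_matrix(mat, "perturbation matrix")
  if (!length(gene_space)) stop("gene_space must be non-empty")
  if (!is.numeric(min_tas) || min_tas < 0 || min_tas > 1) {
    stop("min_tas must be in [0, 1]")
  }
  idx <- match(colnames(mat), metadata$experiment_id)
  if (anyNA(idx)) stop("metadata lacks experiment_id entries for some columns")
  metadata <- metadata[idx, , drop = FALSE]
  tas <- as.numeric(metadata$tas)
  if (anyNA(tas)) stop("metadata$tas must be numeric and complete")

  keep <- tas >= min_tas
  message("filter_perturbations: kept ", sum(keep), " of ", length(keep),
          " experiment(s) at TAS >= ", min_tas)
  genes <- gene_space[gene_space %in% rownames(mat)]
  n_missing <- length(gene_space) - length(genes)
  if (n_missing > 0L) {
    message("filter_perturbations: ", n_missing,
            " gene-space id(s) absent from the matrix")
  }
  if (!length(genes) || !any(keep)) {
    stop("no data left after filtering; review min_tas and gene_space")
  }
  out <- mat[genes, keep, drop = FALSE]
  if (!is.null(.value_kind(mat))) out <- .set_value_kind(out, .value_kind(mat))
  list(matrix = out, metadata = metadata[keep, , drop = FALSE])
}
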