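# Internal helpers shared across modules.

# Coerce user-facing response labels to logical (TRUE = responder).
# Accepts logical, 0/1 numeric, or character/factor with values
# "responder"/"non-responder".
.as_response <- function(labels) {
  if (is.logical(labels)) {
    out <- labels
  } else if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric response labels must be 0 (non-responder) or 1 (responder)")
    }
    out <- labels == 1
  } else {
    labels <- as.character(labels)
    ok <- labels %in% c("responder", "non-responder")
    if (!all(ok)) {
      stop("unrecognised response label(s): ",
           paste(unique(labels[!ok]), collapse = ", "))
    }
    out <- labels == "responder"
  }
  if (anyNA(out)) stop("response labels contain missing values")
  names(out) <- names(labels)
  out
}

.check_both_classes <- function(lab) {
  if (sum(lab) == 0L || sum(!lab) == 0L) {
    stop("both responder and non-responder labels are required")
  }
  invisible(lab)
}

# Extract the gene vector from a gene_signature or character vector.
.as_genes <- function(x) {
  if (inherits(x, "gene_signature")) return(x$genes)
  x <- as.character(x)
  if (!length(x)) stop("empty gene set")
  unique(x)
}

# Overlap rule applied before signature-level enrichment scoring: a
# signature must retain at least `min_genes` members and at least
# `min_frac` of its members inside the ranked universe.
.signature_overlap <- function(universe, genes, min_genes = 15, min_frac = 0.5) {
  genes <- .as_genes(genes)
  n_overlap <- sum(genes %in% universe)
  list(ok = n_overlap >= min_genes && n_overlap >= min_frac * length(genes),
       n_overlap = n_overlap, n_set = length(genes))
}

# value_kind bookkeeping: stored as an attribute on expression matrices.
.value_kind <- function(x) attr(x, "value_kind", exact = TRUE)

.set_value_kind <- function(x, kind) {
  attr(x, "value_kind") <- kind
  x
}

.check_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stop(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(x))) {
    dup <- rownames(x)[duplicated(rownames(x))][1L]
    stop("duplicate gene id in ", what, ": ", dup)
  }
  if (anyDuplicated(colnames(x))) {
    dup <- colnames(x)[duplicated(colnames(x))][1L]
    stop("duplicate sample id in ", what, ": ", dup)
  }
  invisible(x)
}
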