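# GCT 1.3 text reader/writer.  GCT is the carrier format for
# Connectivity-Map level-5 z-score matrices: a version line, a dimension
# line (rows, columns, row-metadata fields, column-metadata fields), a
# header row, one line per column-metadata field, then one line per gene.

# Column-metadata field names are mapped onto the perturbation metadata
# schema; CMAP's own field names are accepted as aliases.
.gct_meta_aliases <- list(
  perturbagen_id   = c("perturbagen_id", "pert_id"),
  perturbagen_type = c("perturbagen_type", "pert_type"),
  target           = c("target", "pert_target", "cmap_name"),
  cell_line        = c("cell_line", "cell_id", "cell_iname"),
  dose             = c("dose", "pert_dose", "pert_idose"),
  tas              = c("tas", "distil_tas")
)

.map_pert_type <- function(x) {
  map <- c(trt_sh = "shRNA", trt_cp = "compound",
           shRNA = "shRNA", compound = "compound")
  out <- unname(map[x])
  ifelse(is.na(out), x, out)
}

#' Read a GCT 1.3 expression matrix
#'
#' Parses a GCT 1.3 (or 1.2) text file into a genes-by-samples numeric
#' matrix plus a per-experiment metadata table assembled from the
#' column-metadata rows.  Metadata fields are mapped onto the perturbation
#' schema (`perturbagen_id`, `perturbagen_type`, `target`, `cell_line`,
#' `dose`, `tas`); CMAP field names (`pert_id`, `pert_type`, `cell_iname`,
#' `distil_tas`, ...) are recognised aliases.  CMAP `pert_type` codes
#' `trt_sh`/`trt_cp` are translated to `shRNA`/`compound`.
#'
#' Genes with any missing value are dropped at read time with a message
#' (no imputation); duplicated gene or sample identifiers are an error.
#'
#' @param path path to a GCT text file.
#' @param value_kind what the numeric values represent; stored as the
#'   `value_kind` attribute of the returned matrix.
#' @return a list with components `matrix` (numeric, genes x samples) and
#'   `metadata` (data frame, one row per sample/experiment with at least
#'   `experiment_id`).
#' @seealso [write_gct()], [filter_perturbations()]
#' @export
read_gct <- function(path,
                     value_kind = c("level5_zscore", "log2_expression",
                                    "delta_log2fc")) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("malformed GCT file (fewer than 3 lines): ", path)
  version <- trimws(lines[1L])
  if (!version %in% c("#1.3", "#1.2")) {
    stop("not a GCT file (first line must be a GCT version tag): ", path)
  }
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "\t")[[1L]]))
  if (version == "#1.3") {
    if (length(dims) != 4L || anyNA(dims)) {
      stop("malformed GCT 1.3 dimension line in ", path)
    }
    nr <- dims[1L]; nc <- dims[2L]; nrhd <- dims[3L]; nchd <- dims[4L]
  } else {
    if (length(dims) != 2L || anyNA(dims)) {
      stop("malformed GCT 1.2 dimension line in ", path)
    }
    nr <- dims[1L]; nc <- dims[2L]; nrhd <- 1L; nchd <- 0L
  }
  if (length(lines) != 3L + nchd + nr) {
    stop("GCT dimension line promises ", nr, " rows and ", nchd,
         " column-metadata lines but file has ", length(lines) - 3L - nchd,
         " data rows: ", path)
  }
  fields <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  width <- 1L + nrhd + nc
  bad <- which(vapply(fields, length, integer(1)) != width)
  if (length(bad)) {
    stop("GCT line ", bad[1L] + 2L, " has ", length(fields[[bad[1L]]]),
         " fields, expected ", width, ": ", path)
  }
  header <- fields[[1L]]
  sample_ids <- header[(1L + nrhd + 1L):width]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id in GCT file: ",
         sample_ids[duplicated(sample_ids)][1L])
  }

  meta <- data.frame(experiment_id = sample_ids, stringsAsFactors = FALSE)
  if (nchd > 0L) {
    for (m in seq_len(nchd)) {
      row <- fields[[1L + m]]
      meta[[row[1L]]] <- row[(1L + nrhd + 1L):width]
    }
    for (canon in names(.gct_meta_aliases)) {
      hit <- intersect(.gct_meta_aliases[[canon]], names(meta))
      if (length(hit)) {
        vals <- meta[[hit[1L]]]
        if (canon == "tas") {
          vals <- suppressWarnings(as.numeric(vals))
          if (any(!is.na(vals) & (vals < 0 | vals > 1))) {
            stop("tas values outside [0, 1] in ", path)
          }
        }
        if (canon == "perturbagen_type") vals <- .map_pert_type(vals)
        meta[[canon]] <- vals
      }
    }
  }

  data_fields <- fields[(1L + nchd + 1L):length(fields)]
  gene_ids <- vapply(data_fields, `[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id in GCT file: ", gene_ids[duplicated(gene_ids)][1L])
  }
  vals <- vapply(data_fields, function(f) {
    suppressWarnings(as.numeric(f[(1L + nrhd + 1L):width]))
  }, numeric(nc))
  mat <- if (nc == 1L) matrix(vals, ncol = 1L) else t(vals)
  dimnames(mat) <- list(gene_ids, sample_ids)

  incomplete <- apply(mat, 1L, anyNA)
  if (any(incomplete)) {
    message("read_gct: dropped ", sum(incomplete),
            " gene(s) with missing values")
    mat <- mat[!incomplete, , drop = FALSE]
  }
  if (nrow(mat) == 0L) stop("no complete gene rows left after reading ", path)
  list(matrix = .set_value_kind(mat, value_kind), metadata = meta)
}

#' Write a GCT 1.3 file
#'
#' @param mat numeric matrix with gene row names and sample column names.
#' @param path output path.
#' @param metadata optional data frame with one row per column of `mat`
#'   (matched on `experiment_id`); all columns except `experiment_id` are
#'   written as column-metadata rows.
#' @return `path`, invisibly.
#' @export
write_gct <- function(mat, path, metadata = NULL) {
  .check_matrix(mat, "GCT matrix")
  nchd <- 0L
  meta_rows <- character(0)
  if (!is.null(metadata)) {
    if (!"experiment_id" %in% names(metadata)) {
      stop("metadata must contain an experiment_id column")
    }
    idx <- match(colnames(mat), metadata$experiment_id)
    if (anyNA(idx)) stop("metadata is missing experiment_id entries for some columns")
    metadata <- metadata[idx, , drop = FALSE]
    keep <- setdiff(names(metadata), "experiment_id")
    nchd <- length(keep)
    meta_rows <- vapply(keep, function(f) {
      paste(c(f, as.character(metadata[[f]])), collapse = "\t")
    }, character(1))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.3", con)
  writeLines(paste(nrow(mat), ncol(mat), 0L, nchd, sep = "\t"), con)
  writeLines(paste(c("id", colnames(mat)), collapse = "\t"), con)
  if (nchd > 0L) writeLines(meta_rows, con)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], sprintf("%.8g", mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}
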