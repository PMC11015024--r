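# GMT gene-set reader/writer: one set per line,
# name <TAB> description <TAB> gene1 <TAB> gene2 ...

#' Read gene sets from a GMT file
#'
#' One gene set per line (`name`, `description`, then genes).  Duplicate
#' genes within a line are removed with a warning; lines with no genes are
#' skipped with a warning; a duplicated set name is an error.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (set name -> unique gene ids).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 2 tab-separated fields")
  }
  nms <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name in GMT file: ", nms[duplicated(nms)][1L])
  }
  sets <- vector("list", length(fields))
  names(sets) <- nms
  for (k in seq_along(fields)) {
    genes <- fields[[k]][-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("set ", nms[k], ": ", sum(duplicated(genes)),
              " duplicated gene(s) removed", call. = FALSE)
      genes <- unique(genes)
    }
    sets[[k]] <- genes
  }
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sum(empty), " empty gene set(s) skipped: ",
            paste(names(sets)[empty], collapse = ", "), call. = FALSE)
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no non-empty gene sets in ", path)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must be a uniquely named list")
  }
  if (any(lengths(sets) == 0L)) stop("every gene set must be non-empty")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(k) {
    paste(c(names(sets)[k], descriptions[k], unique(as.character(sets[[k]]))),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
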