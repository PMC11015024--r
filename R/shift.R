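# Shift-ability screening: score every perturbation experiment for its
# ability to move a cell line from the anti-PD-1-resistant (R) toward the
# -sensitive (S) expression program, call significance, check shRNA
# knockdown success, and integrate the shRNA and compound screens.

#' Shift ability of one perturbation profile
#'
#' Ranks the perturbation's differential-expression profile, computes the
#' normalized enrichment score of the R and S signatures, and returns the
#' shift ability, the deviation of the two: `shift_ability = NES_S -
#' NES_R`.  Positive values mean the perturbation suppresses the R
#' program while inducing the S program (R-to-S shifting).
#'
#' If either signature fails the minimum-overlap rule against the
#' profile's gene universe the result is a flagged row
#' (`insufficient_overlap = TRUE`, scores `NA`) rather than an error, so
#' screens can carry it without aborting.
#'
#' @param profile_column named numeric vector (gene -> differential
#'   value, e.g. a level-5 z-score profile).
#' @param sig_R,sig_S resistance and sensitivity gene sets.
#' @param n_perm,seed,weight passed to [prerank_nes()].
#' @param min_genes,min_frac minimum-overlap rule per signature.
#' @param null_positions optional list with pre-drawn permutation
#'   position matrices `R` and `S` (used by [screen_perturbations()] to
#'   share draws; results identical to drawing under `seed`).
#' @return a `shift_result` list: `es_R`, `es_S`, `nes_R`, `nes_S`,
#'   `p_R`, `p_S`, `shift_ability`, `insufficient_overlap`.
#' @export
compute_shift_ability <- function(profile_column, sig_R, sig_S,
                                  n_perm = 1000, seed = NULL, weight = 1,
                                  min_genes = 15, min_frac = 0.5,
                                  null_positions = NULL) {
  universe <- names(profile_column)[is.finite(profile_column)]
  ovR <- .signature_overlap(universe, sig_R, min_genes, min_frac)
  ovS <- .signature_overlap(universe, sig_S, min_genes, min_frac)
  if (!ovR$ok || !ovS$ok) {
    return(structure(list(es_R = NA_real_, es_S = NA_real_,
                          nes_R = NA_real_, nes_S = NA_real_,
                          p_R = NA_real_, p_S = NA_real_,
                          shift_ability = NA_real_,
                          insufficient_overlap = TRUE),
                     class = "shift_result"))
  }
  ranked <- rank_genes(profile_column)
  r <- prerank_nes(ranked, sig_R, n_perm = n_perm, seed = seed,
                   weight = weight,
                   null_positions = null_positions$R)
  s <- prerank_nes(ranked, sig_S, n_perm = n_perm, seed = seed,
                   weight = weight,
                   null_positions = null_positions$S)
  structure(list(es_R = r$es, es_S = s$es, nes_R = r$nes, nes_S = s$nes,
                 p_R = r$nominal_p, p_S = s$nominal_p,
                 shift_ability = s$nes - r$nes,
                 insufficient_overlap = FALSE),
            class = "shift_result")
}

#' Did an shRNA knock its target down?
#'
#' @param profile_column named numeric differential profile.
#' @param target_gene the shRNA's annotated target.
#' @param kd_threshold knockdown call threshold on the differential
#'   scale; the target counts as knocked down when its value is at or
#'   below the threshold (inclusive).  Default -1.
#' @return logical flag.
#' @export
knockdown_success <- function(profile_column, target_gene, kd_threshold = -1) {
  if (!target_gene %in% names(profile_column)) {
    stop("target gene not in profile: ", target_gene)
  }
  unname(profile_column[target_gene] <= kd_threshold)
}

#' Call significant R-to-S shifting
#'
#' Fixed mode flags rows with `shift_ability >= fixed_threshold`
#' (inclusive; default 3.5, the compound-screen threshold).  Empirical
#' mode flags rows at least `k_sd` standard deviations above the mean of
#' a per-cell-line null distribution: either supplied through
#' `null_scores` (a numeric vector applied to all cell lines, or a named
#' list per cell line), or, when omitted, built from the screen itself as
#' the shift abilities of all other perturbagens in the same cell line
#' (leave-one-perturbagen-out).  Every null must hold at least 30 scores.
#'
#' @param results data frame of screen rows with columns
#'   `shift_ability`, `cell_line` and `perturbagen_id`.
#' @param mode `"fixed"` or `"empirical"`.
#' @param fixed_threshold inclusive threshold for fixed mode.
#' @param null_scores optional empirical null (numeric vector or named
#'   list keyed by cell line).
#' @param k_sd number of null standard deviations for empirical mode.
#' @return `results` with added columns `significant` and
#'   `sig_threshold` (the row's effective threshold).
#' @export
call_significant <- function(results, mode = c("fixed", "empirical"),
                             fixed_threshold = 3.5, null_scores = NULL,
                             k_sd = 2) {
  mode <- match.arg(mode)
  if (!is.data.frame(results) || !"shift_ability" %in% names(results)) {
    stop("results must be a data frame with a shift_ability column")
  }
  if (mode == "fixed") {
    results$sig_threshold <- fixed_threshold
    results$significant <- results$shift_ability >= fixed_threshold
    return(results)
  }
  if (!all(c("cell_line", "perturbagen_id") %in% names(results))) {
    stop("empirical mode needs cell_line and perturbagen_id columns")
  }
  thr <- rep(NA_real_, nrow(results))
  for (r in seq_len(nrow(results))) {
    if (is.na(results$shift_ability[r])) next
    cl <- results$cell_line[r]
    if (!is.null(null_scores)) {
      null <- if (is.list(null_scores)) null_scores[[cl]] else null_scores
      if (is.null(null)) stop("no null scores supplied for cell line ", cl)
    } else {
      null <- results$shift_ability[results$cell_line == cl &
                                    results$perturbagen_id !=
                                      results$perturbagen_id[r] &
                                    !is.na(results$shift_ability)]
    }
    if (length(null) < 30L) {
      stop("empirical mode requires at least 30 null scores per cell line ",
           "(cell line ", cl, " has ", length(null), ")")
    }
    thr[r] <- mean(null) + k_sd * stats::sd(null)
  }
  results$sig_threshold <- thr
  results$significant <- results$shift_ability >= thr
  results
}

#' Screen a perturbation matrix for R-to-S shifting
#'
#' Computes one [compute_shift_ability()] row per experiment column,
#' calls significance, and aggregates per (perturbagen, cell line): a
#' perturbagen shows R-to-S shifting in a cell line when at least one of
#' its experiments there is significant.  Permutation draws are cached
#' per effective signature size so every experiment shares the same
#' seeded null positions; the table is byte-identical across runs with
#' the same seed and identical to computing each row without the cache.
#'
#' @param mat numeric matrix (genes x experiments), already filtered
#'   (see [filter_perturbations()]).
#' @param metadata data frame with one row per experiment
#'   (`experiment_id` matching the columns, `perturbagen_id`,
#'   `perturbagen_type`, `target`, `cell_line`, `tas`).
#' @param sig_R,sig_S resistance and sensitivity gene sets.
#' @param mode,fixed_threshold,k_sd significance rule; see
#'   [call_significant()].  The fixed 3.5 threshold is the compound-screen
#'   default; shRNA screens are typically run in empirical mode.
#' @param n_perm,seed,weight,min_genes,min_frac see
#'   [compute_shift_ability()].
#' @param verbose log progress every 50 experiments.
#' @return a `shift_screen` object: list with `results` (one row per
#'   experiment, including `suppresses_R` = NES_R < 0 and `induces_S` =
#'   NES_S > 0 bookkeeping flags), `aggregates` (per perturbagen and
#'   cell line), and the screening parameters.
#' @export
screen_perturbations <- function(mat, metadata, sig_R, sig_S,
                                 mode = c("fixed", "empirical"),
                                 fixed_threshold = 3.5, k_sd = 2,
                                 n_perm = 1000, seed = 1, weight = 1,
                                 min_genes = 15, min_frac = 0.5,
                                 verbose = FALSE) {
  mode <- match.arg(mode)
  if (ncol(mat) == 0L || nrow(metadata) == 0L) {
    warning("empty perturbation input; returning empty screen", call. = FALSE)
    return(structure(list(results = data.frame(), aggregates = data.frame(),
                          mode = mode, seed = seed),
                     class = "shift_screen"))
  }
  .check_matrix(mat, "perturbation matrix")
  idx <- match(colnames(mat), metadata$experiment_id)
  if (anyNA(idx)) stop("metadata lacks experiment_id entries for some columns")
  metadata <- metadata[idx, , drop = FALSE]
  for (col in c("perturbagen_id", "perturbagen_type", "cell_line")) {
    if (is.null(metadata[[col]])) metadata[[col]] <- NA_character_
  }
  if (is.null(metadata$target)) metadata$target <- NA_character_

  cache <- new.env(parent = emptyenv())
  get_positions <- function(N, k) {
    key <- paste(N, k, sep = ":")
    if (is.null(cache[[key]])) {
      cache[[key]] <- .draw_null_positions(N, k, n_perm, seed)
    }
    cache[[key]]
  }

  rows <- vector("list", ncol(mat))
  for (e in seq_len(ncol(mat))) {
    prof <- mat[, e]
    universe <- names(prof)[is.finite(prof)]
    N <- length(universe)
    kR <- sum(.as_genes(sig_R) %in% universe)
    kS <- sum(.as_genes(sig_S) %in% universe)
    np <- if (kR > 0L && kS > 0L && kR < N && kS < N) {
      list(R = get_positions(N, kR), S = get_positions(N, kS))
    } else NULL
    sr <- compute_shift_ability(prof, sig_R, sig_S, n_perm = n_perm,
                                seed = seed, weight = weight,
                                min_genes = min_genes, min_frac = min_frac,
                                null_positions = np)
    rows[[e]] <- data.frame(
      experiment_id = colnames(mat)[e],
      perturbagen_id = metadata$perturbagen_id[e],
      perturbagen_type = metadata$perturbagen_type[e],
      target = metadata$target[e],
      cell_line = metadata$cell_line[e],
      es_R = sr$es_R, es_S = sr$es_S,
      nes_R = sr$nes_R, nes_S = sr$nes_S,
      p_R = sr$p_R, p_S = sr$p_S,
      shift_ability = sr$shift_ability,
      insufficient_overlap = sr$insufficient_overlap,
      stringsAsFactors = FALSE)
    if (verbose && e %% 50 == 0) {
      message("screen_perturbations: ", e, "/", ncol(mat), " experiments scored")
    }
  }
  res <- do.call(rbind, rows)
  res$suppresses_R <- res$nes_R < 0
  res$induces_S <- res$nes_S > 0
  res <- call_significant(res, mode = mode, fixed_threshold = fixed_threshold,
                          k_sd = k_sd)

  ok <- !res$insufficient_overlap & !is.na(res$significant)
  agg <- if (any(ok)) {
    sub <- res[ok, , drop = FALSE]
    key <- interaction(sub$perturbagen_id, sub$cell_line, drop = TRUE)
    parts <- split(sub, key)
    do.call(rbind, lapply(parts, function(p) {
      data.frame(perturbagen_id = p$perturbagen_id[1L],
                 cell_line = p$cell_line[1L],
                 n_experiments = nrow(p),
                 n_significant = sum(p$significant),
                 fraction_significant = mean(p$significant),
                 any_significant = any(p$significant),
                 stringsAsFactors = FALSE)
    }))
  } else data.frame()
  rownames(agg) <- NULL
  structure(list(results = res, aggregates = agg, mode = mode,
                 fixed_threshold = fixed_threshold, k_sd = k_sd,
                 n_perm = n_perm, seed = seed),
            class = "shift_screen")
}

#' @export
print.shift_screen <- function(x, ...) {
  cat("Shift-ability screen (", x$mode, " significance mode)\n", sep = "")
  if (!nrow(x$results)) {
    cat("  empty screen\n")
    return(invisible(x))
  }
  cat(sprintf("  %d experiments, %d flagged insufficient overlap\n",
              nrow(x$results), sum(x$results$insufficient_overlap)))
  cat(sprintf("  %d significant R-to-S shifting experiments\n",
              sum(x$results$significant, na.rm = TRUE)))
  cat(sprintf("  %d perturbagen/cell-line groups, %d with >= 1 significant experiment\n",
              nrow(x$aggregates), sum(x$aggregates$any_significant)))
  invisible(x)
}

#' @export
summary.shift_screen <- function(object, ...) {
  print(object)
  if (nrow(object$results)) {
    cat("\nShift-ability distribution:\n")
    print(summary(object$results$shift_ability))
  }
  invisible(object)
}

#' @export
as.data.frame.shift_screen <- function(x, ...) x$results

#' Integrate shRNA and compound screens into consistent synergy targets
#'
#' A gene is a consistent synergy target when, in at least one cell line,
#' both an shRNA targeting the gene and a compound annotated to the gene
#' show significant R-to-S shifting.  Compounds without a target
#' annotation are skipped with a message.
#'
#' @param shrna_table,compound_table `shift_screen` objects (or their
#'   `results` data frames).
#' @param compound_targets named list mapping compound perturbagen ids to
#'   character vectors of annotated target genes.
#' @return list with `genes` (sorted character vector) and `evidence`
#'   (data frame of supporting gene / cell line / experiment triples).
#' @export
integrate_screens <- function(shrna_table, compound_table, compound_targets) {
  as_rows <- function(x) if (inherits(x, "shift_screen")) x$results else x
  sh <- as_rows(shrna_table)
  cp <- as_rows(compound_table)
  empty <- list(genes = character(0),
                evidence = data.frame(gene = character(0),
                                      cell_line = character(0),
                                      shrna_experiment = character(0),
                                      compound_experiment = character(0),
                                      stringsAsFactors = FALSE))
  if (!nrow(sh) || !nrow(cp)) return(empty)
  sh <- sh[!is.na(sh$significant) & sh$significant & !is.na(sh$target), ,
           drop = FALSE]
  cp <- cp[!is.na(cp$significant) & cp$significant, , drop = FALSE]
  if (!nrow(sh) || !nrow(cp)) return(empty)

  no_ann <- setdiff(unique(cp$perturbagen_id), names(compound_targets))
  if (length(no_ann)) {
    message("integrate_screens: skipped ", length(no_ann),
            " compound(s) without target annotation")
    cp <- cp[cp$perturbagen_id %in% names(compound_targets), , drop = FALSE]
  }
  if (!nrow(cp)) return(empty)
  cp_long <- do.call(rbind, lapply(seq_len(nrow(cp)), function(r) {
    genes <- compound_targets[[cp$perturbagen_id[r]]]
    if (!length(genes)) return(NULL)
    data.frame(gene = genes, cell_line = cp$cell_line[r],
               compound_experiment = cp$experiment_id[r],
               stringsAsFactors = FALSE)
  }))
  if (is.null(cp_long) || !nrow(cp_long)) return(empty)
  sh_long <- data.frame(gene = sh$target, cell_line = sh$cell_line,
                        shrna_experiment = sh$experiment_id,
                        stringsAsFactors = FALSE)
  ev <- merge(sh_long, cp_long, by = c("gene", "cell_line"))
  ev <- ev[order(ev$gene, ev$cell_line, ev$shrna_experiment,
                 ev$compound_experiment), , drop = FALSE]
  rownames(ev) <- NULL
  list(genes = sort(unique(ev$gene)), evidence = ev)
}
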