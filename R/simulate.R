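# Synthetic-data generators with known ground truth.  They emulate the
# statistical structure the pipeline assumes — paired log2 cohorts with
# planted response-separating genes, level-5-like z-score perturbation
# profiles with planted R-to-S shifting treatments, and compound families
# sharing mechanism templates — so the full stack is testable without any
# external download.  Every generator is a pure function of its
# parameters, seed included.

#' Simulate a paired anti-PD-1 cohort with planted R/S genes
#'
#' Pre-treatment expression is N(8, 1) per gene and sample on the log2
#' scale; on-treatment expression adds N(0, `noise_sd`) noise, so the
#' treatment-induced change of an unplanted gene is pure noise.  Planted
#' resistance genes gain an extra `effect_size` (in units of the
#' within-group change SD) in non-responders, planted sensitivity genes
#' the same in responders.
#'
#' @param n_genes,n_planted_R,n_planted_S universe and planted-set sizes;
#'   defaults 5000 genes with 200 planted per direction.
#' @param n_responders,n_nonresponders patients per class; default 20
#'   each.
#' @param effect_size between-group mean shift of the change, in
#'   within-group SD units; default 1.5.
#' @param noise_sd SD of the treatment-induced change noise; default 1.
#' @param seed integer seed.
#' @return list with `cohort` (a [paired_cohort()]) and `truth` (planted
#'   `R` and `S` gene ids).
#' @export
simulate_cohort <- function(n_genes = 5000, n_planted_R = 200,
                            n_planted_S = 200, n_responders = 20,
                            n_nonresponders = 20, effect_size = 1.5,
                            noise_sd = 1, seed = 1) {
  stopifnot(n_genes > 0, n_planted_R > 0, n_planted_S > 0,
            n_responders > 0, n_nonresponders > 0, effect_size >= 0,
            noise_sd > 0, n_planted_R + n_planted_S <= n_genes)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  planted_R <- sample(genes, n_planted_R)
  planted_S <- sample(setdiff(genes, planted_R), n_planted_S)
  n_pat <- n_responders + n_nonresponders
  patients <- sprintf("pat%03d", seq_len(n_pat))
  response <- stats::setNames(
    c(rep("responder", n_responders), rep("non-responder", n_nonresponders)),
    patients)

  pre <- matrix(stats::rnorm(n_genes * n_pat, mean = 8, sd = 1),
                nrow = n_genes, dimnames = list(genes, patients))
  delta <- matrix(stats::rnorm(n_genes * n_pat, mean = 0, sd = noise_sd),
                  nrow = n_genes, dimnames = list(genes, patients))
  is_resp <- response == "responder"
  delta[planted_R, !is_resp] <- delta[planted_R, !is_resp] +
    effect_size * noise_sd
  delta[planted_S, is_resp] <- delta[planted_S, is_resp] +
    effect_size * noise_sd
  post <- pre + delta

  list(cohort = paired_cohort(pre, post, response),
       truth = list(R = sort(planted_R), S = sort(planted_S)))
}

#' Simulate a level-5-like perturbation screen with planted shifters
#'
#' Null experiments are N(0, `background_sd`) z-score profiles.  Planted
#' experiments add `+planted_magnitude` on a set of S-like up-genes and
#' `-planted_magnitude` on a disjoint set of R-like down-genes, i.e. they
#' suppress the R program and induce the S program.  Metadata rows are
#' synthesized with alternating shRNA/compound types, round-robin cell
#' lines, one perturbagen per experiment, and TAS drawn uniformly from
#' [0.4, 1] (a configurable fraction is drawn below 0.4 to exercise the
#' TAS filter).
#'
#' @param n_genes universe size; default 5000.
#' @param n_null,n_planted numbers of null and planted experiments;
#'   defaults 100 and 10.
#' @param planted_up,planted_down gene sets for the planted effect;
#'   defaults are disjoint random sets of `n_planted_genes`.
#' @param n_planted_genes size of each default planted set; default 100.
#' @param planted_magnitude z-score offset of the planted effect;
#'   default 2.
#' @param background_sd z-score noise SD; default 1.
#' @param n_cell_lines number of round-robin cell lines; default 2.
#' @param low_tas_fraction fraction of experiments with TAS below 0.4;
#'   default 0.
#' @param seed integer seed.
#' @return list with `matrix` (genes x experiments), `metadata` (one row
#'   per experiment), and `truth` (planted experiment ids, the planted
#'   gene sets).
#' @export
simulate_perturbations <- function(n_genes = 5000, n_null = 100,
                                   n_planted = 10, planted_up = NULL,
                                   planted_down = NULL,
                                   n_planted_genes = 100,
                                   planted_magnitude = 2, background_sd = 1,
                                   n_cell_lines = 2, low_tas_fraction = 0,
                                   seed = 1) {
  stopifnot(n_genes > 0, n_null >= 0, n_planted >= 0,
            planted_magnitude >= 0, background_sd > 0, n_cell_lines >= 1,
            low_tas_fraction >= 0, low_tas_fraction <= 1)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  if (is.null(planted_up)) planted_up <- sample(genes, n_planted_genes)
  if (is.null(planted_down)) {
    planted_down <- sample(setdiff(genes, planted_up), n_planted_genes)
  }
  if (length(intersect(planted_up, planted_down))) {
    stop("planted_up and planted_down must be disjoint")
  }
  n_exp <- n_null + n_planted
  exp_ids <- sprintf("exp%04d", seq_len(n_exp))
  planted_ids <- if (n_planted > 0) exp_ids[(n_null + 1):n_exp] else character(0)

  mat <- matrix(stats::rnorm(n_genes * n_exp, sd = background_sd),
                nrow = n_genes, dimnames = list(genes, exp_ids))
  if (n_planted > 0) {
    mat[planted_up, planted_ids] <- mat[planted_up, planted_ids] +
      planted_magnitude
    mat[planted_down, planted_ids] <- mat[planted_down, planted_ids] -
      planted_magnitude
  }
  mat <- .set_value_kind(mat, "level5_zscore")

  type <- rep(c("shRNA", "compound"), length.out = n_exp)
  target <- ifelse(type == "shRNA",
                   sample(genes, n_exp, replace = TRUE), NA_character_)
  tas <- stats::runif(n_exp, 0.4, 1)
  if (low_tas_fraction > 0) {
    low <- sample(n_exp, round(n_exp * low_tas_fraction))
    tas[low] <- stats::runif(length(low), 0, 0.4 - 1e-9)
  }
  metadata <- data.frame(
    experiment_id = exp_ids,
    perturbagen_id = sprintf("pert%04d", seq_len(n_exp)),
    perturbagen_type = type,
    target = target,
    cell_line = sprintf("CL%d", (seq_len(n_exp) - 1L) %% n_cell_lines + 1L),
    dose = ifelse(type == "compound", "10 uM", NA_character_),
    tas = tas,
    stringsAsFactors = FALSE)

  list(matrix = mat, metadata = metadata,
       truth = list(shifting_experiments = planted_ids,
                    planted_up = sort(planted_up),
                    planted_down = sort(planted_down)))
}

#' Simulate compound families sharing mechanism templates
#'
#' Each template is a signed gene map (values +/-2 on its template
#' genes); each compound of a template produces `n_experiments`
#' differential profiles equal to the template plus N(0, `noise_sd`)
#' noise.  Templates must be disjoint in their signed gene sets.
#'
#' @param n_compounds_per_template compounds per template; default 10.
#' @param templates list of named numeric vectors (gene -> +/-2); default
#'   two disjoint templates of 150 genes each (half up, half down) over a
#'   1000-gene universe.
#' @param n_genes universe size used when `templates` is NULL.
#' @param n_template_genes template size used when `templates` is NULL.
#' @param n_experiments experiments per compound; default 3.
#' @param noise_sd profile noise SD; default 0.5.
#' @param seed integer seed.
#' @return list with `profiles` (named list: compound -> genes x
#'   experiments matrix), `truth` (named integer template label per
#'   compound), `templates`, and `genes`.
#' @export
simulate_mechanism_matrix <- function(n_compounds_per_template = 10,
                                      templates = NULL, n_genes = 1000,
                                      n_template_genes = 150,
                                      n_experiments = 3, noise_sd = 0.5,
                                      seed = 1) {
  stopifnot(n_compounds_per_template >= 1, n_experiments >= 1, noise_sd >= 0)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  if (is.null(templates)) {
    pick <- sample(genes, 2L * n_template_genes)
    half <- function(g) {
      n_up <- ceiling(length(g) / 2)
      stats::setNames(c(rep(2, n_up), rep(-2, length(g) - n_up)), g)
    }
    templates <- list(template1 = half(pick[seq_len(n_template_genes)]),
                      template2 = half(pick[(n_template_genes + 1):
                                              (2L * n_template_genes)]))
  } else {
    genes <- unique(c(genes, unlist(lapply(templates, names))))
    all_t <- unlist(lapply(templates, names))
    if (anyDuplicated(all_t)) {
      stop("templates must be disjoint in their signed gene sets")
    }
  }
  n_templates <- length(templates)
  compounds <- sprintf("cmp%03d", seq_len(n_templates * n_compounds_per_template))
  truth <- stats::setNames(rep(seq_len(n_templates),
                               each = n_compounds_per_template), compounds)

  profiles <- lapply(seq_along(compounds), function(ci) {
    tmpl <- templates[[truth[ci]]]
    base <- stats::setNames(numeric(length(genes)), genes)
    base[names(tmpl)] <- tmpl
    m <- matrix(stats::rnorm(length(genes) * n_experiments, sd = noise_sd),
                nrow = length(genes),
                dimnames = list(genes, sprintf("%s_e%d", compounds[ci],
                                               seq_len(n_experiments))))
    m + base
  })
  names(profiles) <- compounds
  list(profiles = profiles, truth = truth, templates = templates,
       genes = genes)
}
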