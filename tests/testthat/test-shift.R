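# Shift-ability scoring, significance calls, screening and screen
# integration.

planted_profile <- function(seed = 41, n_genes = 500, n_set = 40, mag = 2) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  up <- sample(genes, n_set)
  down <- sample(setdiff(genes, up), n_set)
  x <- setNames(rnorm(n_genes), genes)
  x[up] <- x[up] + mag
  x[down] <- x[down] - mag
  list(profile = x, up = up, down = down)
}

test_that("shift ability is exactly NES_S minus NES_R", {
  pp <- planted_profile()
  sr <- compute_shift_ability(pp$profile, sig_R = pp$down, sig_S = pp$up,
                              n_perm = 200, seed = 3)
  expect_identical(sr$shift_ability, sr$nes_S - sr$nes_R)
  expect_gt(sr$shift_ability, 0)
  expect_false(sr$insufficient_overlap)
  # same signature on both sides cancels exactly
  same <- compute_shift_ability(pp$profile, pp$up, pp$up,
                                n_perm = 200, seed = 3)
  expect_identical(same$shift_ability, 0)
  # swapping the signatures negates the score exactly (same seeded nulls)
  sw <- compute_shift_ability(pp$profile, sig_R = pp$up, sig_S = pp$down,
                              n_perm = 200, seed = 3)
  expect_identical(sw$shift_ability, -(sr$shift_ability))
})

test_that("negating the profile flips enrichment", {
  pp <- planted_profile(seed = 42)
  r1 <- rank_genes(pp$profile)
  r2 <- rank_genes(-pp$profile)
  expect_equal(prerank_es(r2, pp$up), -prerank_es(r1, pp$up),
               tolerance = 1e-12)
  expect_equal(prerank_es(r2, pp$down), -prerank_es(r1, pp$down),
               tolerance = 1e-12)
  sr <- compute_shift_ability(pp$profile, pp$down, pp$up, n_perm = 500, seed = 4)
  nr <- compute_shift_ability(-pp$profile, pp$down, pp$up, n_perm = 500, seed = 4)
  expect_lt(nr$shift_ability, 0)
  # NES normalization is a fresh draw on the reversed list, so the
  # magnitude matches only statistically
  expect_equal(nr$shift_ability, -sr$shift_ability,
               tolerance = 0.15 * abs(sr$shift_ability))
})

test_that("insufficient signature overlap yields a flagged row, not an error", {
  pp <- planted_profile()
  sr <- compute_shift_ability(pp$profile, sig_R = c("none1", "none2"),
                              sig_S = pp$up, n_perm = 200, seed = 1)
  expect_true(sr$insufficient_overlap)
  expect_true(is.na(sr$shift_ability))
})

test_that("knockdown success is an inclusive threshold on the target value", {
  prof <- c(A = -2, B = 0.5, C = -1)
  expect_true(knockdown_success(prof, "A"))
  expect_false(knockdown_success(prof, "B"))
  expect_true(knockdown_success(prof, "C"))   # boundary -1 is inclusive
  expect_error(knockdown_success(prof, "D"), "D")
})

test_that("significance calls: fixed threshold inclusive, empirical from nulls", {
  res <- data.frame(shift_ability = c(3.6, 3.5, 3.4),
                    cell_line = "A", perturbagen_id = c("x", "y", "z"),
                    stringsAsFactors = FALSE)
  out <- call_significant(res, mode = "fixed")
  expect_identical(out$significant, c(TRUE, TRUE, FALSE))

  set.seed(43)
  null <- rnorm(100)
  res2 <- data.frame(shift_ability = c(5, 0.5),
                     cell_line = "A", perturbagen_id = c("x", "y"),
                     stringsAsFactors = FALSE)
  out2 <- call_significant(res2, mode = "empirical", null_scores = null)
  expect_true(out2$significant[1])
  expect_false(out2$significant[2])
  expect_equal(out2$sig_threshold[1], mean(null) + 2 * sd(null))
  expect_error(call_significant(res2, mode = "empirical",
                                null_scores = rnorm(10)), "at least 30")
  # leave-one-perturbagen-out null excludes the row's own perturbagen
  set.seed(44)
  res3 <- data.frame(shift_ability = c(rnorm(40), 8),
                     cell_line = "B",
                     perturbagen_id = sprintf("p%02d", 1:41),
                     stringsAsFactors = FALSE)
  out3 <- call_significant(res3, mode = "empirical")
  loo <- res3$shift_ability[-41]
  expect_equal(out3$sig_threshold[41], mean(loo) + 2 * sd(loo))
  expect_true(out3$significant[41])
})

test_that("screening aggregates per perturbagen and is byte-identical under a seed", {
  pp <- planted_profile(seed = 45, n_genes = 300, n_set = 30)
  set.seed(46)
  n_null <- 5
  mat <- cbind(
    vapply(seq_len(n_null), function(i) rnorm(300), numeric(300)),
    pp$profile, pp$profile + rnorm(300, sd = 0.1), rnorm(300))
  rownames(mat) <- names(pp$profile)
  colnames(mat) <- sprintf("e%d", 1:8)
  meta <- data.frame(
    experiment_id = colnames(mat),
    perturbagen_id = c(sprintf("null%d", 1:5), "cmpA", "cmpA", "cmpA"),
    perturbagen_type = "compound", target = NA_character_,
    cell_line = "A375", tas = 0.9, stringsAsFactors = FALSE)
  scr <- screen_perturbations(mat, meta, sig_R = pp$down, sig_S = pp$up,
                              mode = "fixed", fixed_threshold = 3.5,
                              n_perm = 200, seed = 5)
  agg <- scr$aggregates[scr$aggregates$perturbagen_id == "cmpA", ]
  expect_identical(agg$n_experiments, 3L)
  # first two cmpA experiments carry the planted shift, the third is null
  expect_identical(agg$n_significant, 2L)
  expect_equal(agg$fraction_significant, 2 / 3)
  expect_true(agg$any_significant)
  expect_identical(scr$results$shift_ability,
                   scr$results$nes_S - scr$results$nes_R)

  scr2 <- screen_perturbations(mat, meta, sig_R = pp$down, sig_S = pp$up,
                               mode = "fixed", fixed_threshold = 3.5,
                               n_perm = 200, seed = 5)
  expect_identical(scr, scr2)

  # the shared permutation cache changes nothing vs direct scoring
  direct <- compute_shift_ability(mat[, "e6"], pp$down, pp$up,
                                  n_perm = 200, seed = 5)
  row6 <- scr$results[scr$results$experiment_id == "e6", ]
  expect_identical(row6$nes_R, direct$nes_R)
  expect_identical(row6$nes_S, direct$nes_S)
  expect_identical(row6$shift_ability, direct$shift_ability)
})

test_that("empty screening input returns an empty table with a warning", {
  expect_warning(
    scr <- screen_perturbations(matrix(numeric(0), 0, 0), data.frame(),
                                sig_R = "a", sig_S = "b"),
    "empty")
  expect_identical(nrow(scr$results), 0L)
})

test_that("screen integration requires shRNA and compound evidence in one cell line", {
  sh <- data.frame(
    experiment_id = c("sh1", "sh2", "sh3"),
    perturbagen_id = c("shG", "shG", "shH"),
    target = c("G", "G", "H"),
    cell_line = c("A375", "MCF7", "A375"),
    significant = c(TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  cp <- data.frame(
    experiment_id = c("c1", "c2", "c3"),
    perturbagen_id = c("drugG", "drugH", "drugX"),
    target = NA_character_,
    cell_line = c("A375", "MCF7", "A375"),
    significant = c(TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  targets <- list(drugG = "G", drugH = "H")
  got <- suppressMessages(integrate_screens(sh, cp, targets))
  # G: shRNA and compound both significant in A375 -> retained
  # H: shRNA significant in A375 but compound only in MCF7 -> dropped
  # drugX has no annotation -> skipped
  expect_identical(got$genes, "G")
  expect_identical(nrow(got$evidence), 1L)
  expect_identical(got$evidence$cell_line, "A375")
  expect_identical(got$evidence$shrna_experiment, "sh1")
  expect_identical(got$evidence$compound_experiment, "c1")
  expect_message(integrate_screens(sh, cp, targets), "without target")
})
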