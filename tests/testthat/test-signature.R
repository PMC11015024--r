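# Bootstrapped DEG selection, candidate signatures and the
# cross-validated signature fit.

test_that("vectorized row t-test matches stats::t.test", {
  set.seed(21)
  m <- matrix(rnorm(60), 5, 12, dimnames = list(sprintf("g%d", 1:5),
                                                sprintf("p%d", 1:12)))
  i1 <- 1:5; i2 <- 6:12
  eq <- shiftability:::.row_ttest(m, i1, i2, welch = FALSE)
  we <- shiftability:::.row_ttest(m, i1, i2, welch = TRUE)
  for (g in 1:5) {
    ref_eq <- t.test(m[g, i1], m[g, i2], var.equal = TRUE)
    ref_we <- t.test(m[g, i1], m[g, i2], var.equal = FALSE)
    expect_equal(eq$p[g], ref_eq$p.value, tolerance = 1e-12)
    expect_equal(we$p[g], ref_we$p.value, tolerance = 1e-12)
    expect_equal(eq$diff[g], mean(m[g, i1]) - mean(m[g, i2]),
                 tolerance = 1e-12)
  }
})

test_that("hit fractions are bookkept per direction and seeded", {
  set.seed(22)
  d <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("p%d", 1:12)))
  lab <- rep(c("responder", "non-responder"), each = 6)
  sc <- bootstrap_deg_selection(d, lab, n_boot = 20, seed = 4)
  expect_true(all(sc$hit_fraction_R + sc$hit_fraction_S <= 1))
  ints <- 20 * (sc$hit_fraction_R + sc$hit_fraction_S)
  expect_equal(ints, round(ints), tolerance = 1e-12)
  expect_identical(sc, bootstrap_deg_selection(d, lab, n_boot = 20, seed = 4))
  expect_identical(attr(sc, "n_boot"), 20)
  # zero-variance gene is never a hit
  d2 <- rbind(d, flat = 0)
  sc2 <- bootstrap_deg_selection(d2, lab, n_boot = 20, seed = 4)
  expect_equal(sc2$hit_fraction_R[sc2$gene == "flat"], 0)
  expect_equal(sc2$hit_fraction_S[sc2$gene == "flat"], 0)
  expect_error(bootstrap_deg_selection(d[, 1:5], lab[1:5], seed = 1),
               "at least 3")
})

test_that("a strongly separated gene is hit in nearly every resample", {
  set.seed(23)
  n <- 15
  d <- matrix(rnorm(50 * 2 * n), 50, 2 * n,
              dimnames = list(sprintf("g%02d", 1:50),
                              sprintf("p%02d", 1:(2 * n))))
  lab <- rep(c("responder", "non-responder"), each = n)
  d["g01", lab == "non-responder"] <- d["g01", lab == "non-responder"] + 3
  sc <- bootstrap_deg_selection(d, lab, n_boot = 100, seed = 5)
  expect_gte(sc$hit_fraction_R[sc$gene == "g01"], 0.95)
  expect_equal(sc$hit_fraction_S[sc$gene == "g01"], 0)
})

test_that("candidate signatures take the top percent with boundary ties", {
  fr <- c(stats::setNames(seq(0.99, 0.50, length.out = 50),
                          sprintf("r%02d", 1:50)), x1 = 0, x2 = 0)
  fs <- stats::setNames(c(0.9, 0.8, 0.8, 0.1), sprintf("s%d", 1:4))
  sc <- structure(
    data.frame(gene = c(names(fr), names(fs)),
               hit_fraction_R = c(fr, rep(0, 4)),
               hit_fraction_S = c(rep(0, 52), fs),
               stringsAsFactors = FALSE),
    class = c("deg_selection", "data.frame"), n_boot = 100, alpha = 0.05)
  got <- candidate_signatures(sc, i = 10, j = 50)
  expect_identical(sort(got$R$genes), sprintf("r%02d", 1:5))
  # 50% of 4 positive S genes = 2, but the 0.8 boundary tie is included
  expect_identical(sort(got$S$genes), c("s1", "s2", "s3"))
  all_of_them <- candidate_signatures(sc, i = 100, j = 100)
  expect_identical(sort(all_of_them$R$genes), sort(names(fr)[fr > 0]))
  # enlarging i never shrinks the signature
  prev <- character(0)
  for (i in c(5, 20, 60, 100)) {
    cur <- candidate_signatures(sc, i = i, j = 100)$R$genes
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  sc$hit_fraction_S[] <- 0
  expect_error(candidate_signatures(sc, 10, 10), "positive S hit")
})

test_that("the cross-validated fit is deterministic and structurally sound", {
  sim <- small_cohort(seed = 31)
  d <- treatment_induced_changes(sim$cohort)
  grid <- expand.grid(i = c(10, 30, 50), j = c(10, 30, 50))
  fit <- cross_validate_signatures(d, sim$cohort$response, grid = grid,
                                   n_boot = 50, seed = 2)
  fit2 <- cross_validate_signatures(d, sim$cohort$response, grid = grid,
                                    n_boot = 50, seed = 2)
  expect_identical(fit[setdiff(names(fit), "call")],
                   fit2[setdiff(names(fit2), "call")])
  expect_true(fit$chosen_i %in% grid$i && fit$chosen_j %in% grid$j)
  expect_identical(nrow(fit$grid), nrow(grid))
  # core signatures are the intersection of the fold candidates
  if (!fit$core_fallback) {
    for (f in seq_along(fit$fold_candidates)) {
      expect_true(all(fit$core_R$genes %in% fit$fold_candidates[[f]]$R))
      expect_true(all(fit$core_S$genes %in% fit$fold_candidates[[f]]$S))
    }
  }
  expect_true(all(fit$grid$cv_auc >= 0 & fit$grid$cv_auc <= 1, na.rm = TRUE))
  # methods
  expect_output(print(fit), "core signatures")
  cf <- coef(fit)
  expect_identical(cf$R, fit$core_R$genes)
  sc <- predict(fit, d[, 1:3])
  expect_identical(names(sc), colnames(d)[1:3])
  expect_equal(unname(sc[1]),
               rs_score(rank_genes(d[, 1]), fit$core_R$genes,
                        fit$core_S$genes))
  cls <- predict(fit, d[, 1:3], type = "class")
  expect_true(all(cls %in% c("responder", "non-responder")))
})

test_that("planted truth scores the cohort accurately; swapping inverts it", {
  sim <- small_cohort(seed = 32)
  d <- treatment_induced_changes(sim$cohort)
  lab <- sim$cohort$response
  auc <- evaluate_signature(d, lab, sim$truth$R, sim$truth$S)
  expect_gte(auc, 0.9)
  expect_equal(evaluate_signature(d, lab, sim$truth$S, sim$truth$R),
               1 - auc, tolerance = 1e-12)
  # random same-size signatures carry no signal
  set.seed(33)
  decoy_R <- sample(rownames(d), length(sim$truth$R))
  decoy_S <- sample(setdiff(rownames(d), decoy_R), length(sim$truth$S))
  null_auc <- evaluate_signature(d, lab, decoy_R, decoy_S)
  expect_gt(null_auc, 0.2)
  expect_lt(null_auc, 0.8)
  expect_error(evaluate_signature(d, lab, c("zz1", "zz2"), sim$truth$S),
               "insufficient overlap")
})
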