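# GCT / GMT / cohort-table readers and the perturbation filters.

make_meta <- function(n, tas = NULL) {
  data.frame(experiment_id = sprintf("s%d", seq_len(n)),
             perturbagen_id = sprintf("p%d", seq_len(n)),
             perturbagen_type = rep(c("shRNA", "compound"), length.out = n),
             cell_line = "A375",
             tas = if (is.null(tas)) rep(0.8, n) else tas,
             stringsAsFactors = FALSE)
}

test_that("GCT 1.3 write-then-read preserves ids, values and metadata", {
  mat <- matrix(c(1.25, -0.5, 2.718281828, 0), 2, 2,
                dimnames = list(c("TP53", "MYC"), c("s1", "s2")))
  meta <- make_meta(2, tas = c(0.45, 0.91))
  f <- withr::local_tempfile(fileext = ".gct")
  write_gct(mat, f, metadata = meta)
  got <- read_gct(f)
  expect_identical(rownames(got$matrix), c("TP53", "MYC"))
  expect_identical(colnames(got$matrix), c("s1", "s2"))
  expect_equal(unname(got$matrix), unname(mat), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(got$metadata$tas, c(0.45, 0.91))
  expect_identical(got$metadata$perturbagen_type, c("shRNA", "compound"))
  expect_identical(attr(got$matrix, "value_kind"), "level5_zscore")
  # re-writing what was read reproduces the same matrix
  f2 <- withr::local_tempfile(fileext = ".gct")
  write_gct(got$matrix, f2, metadata = got$metadata)
  expect_equal(read_gct(f2)$matrix, got$matrix, tolerance = 1e-6)
})

test_that("GCT reader maps CMAP-style metadata aliases", {
  f <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.3", "2\t2\t0\t3",
               "id\te1\te2",
               "pert_type\ttrt_sh\ttrt_cp",
               "cell_iname\tA375\tMCF7",
               "distil_tas\t0.5\t0.9",
               "g1\t1\t2", "g2\t3\t4"), f)
  got <- read_gct(f)
  expect_identical(got$metadata$perturbagen_type, c("shRNA", "compound"))
  expect_identical(got$metadata$cell_line, c("A375", "MCF7"))
  expect_equal(got$metadata$tas, c(0.5, 0.9))
})

test_that("GCT integrity and parse failures are informative", {
  f <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.3", "2\t1\t0\t0", "id\ts1", "TP53\t1", "TP53\t2"), f)
  expect_error(read_gct(f), "TP53")
  writeLines(c("#1.3", "2\tx\t0\t0", "id\ts1", "g1\t1", "g2\t2"), f)
  expect_error(read_gct(f), "dimension")
  writeLines(c("#1.3", "3\t1\t0\t0", "id\ts1", "g1\t1", "g2\t2"), f)
  expect_error(read_gct(f), "promises")
  writeLines(c("not-a-gct", "1\t1\t0\t0", "id\ts1", "g1\t1"), f)
  expect_error(read_gct(f), "version tag")
})

test_that("genes with missing values are dropped at read time", {
  f <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.3", "2\t2\t0\t0", "id\ts1\ts2",
               "g1\t1\tNA", "g2\t3\t4"), f)
  expect_message(got <- read_gct(f), "1 gene")
  expect_identical(rownames(got$matrix), "g2")
})

test_that("GMT parsing: dedup warning, empty-set skip, duplicate-name error", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tg1\tg2",
               "SETB\tdesc\tg1\tg1\tg3",
               "EMPTY\tdesc"), f)
  expect_warning(expect_warning(sets <- read_gmt(f), "duplicated gene"),
                 "empty gene set")
  expect_identical(sets$SETA, c("g1", "g2"))
  expect_identical(sets$SETB, c("g1", "g3"))
  expect_false("EMPTY" %in% names(sets))

  writeLines(c("SETA\tdesc\tg1", "SETA\tdesc\tg2"), f)
  expect_error(read_gmt(f), "duplicate gene-set name")

  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f2)
  expect_identical(read_gmt(f2), sets)
})

write_cohort_fixture <- function(clin_extra = NULL) {
  genes <- sprintf("g%d", 1:4)
  samples <- c("a_pre", "a_post", "b_pre", "b_post", "c_pre", "d_pre", "d_post")
  set.seed(42)
  expr <- matrix(round(rnorm(length(genes) * length(samples), 8), 3),
                 nrow = length(genes), dimnames = list(genes, samples))
  clin <- data.frame(
    sample_id = samples,
    patient_id = rep(c("a", "b", "c", "d"), c(2, 2, 1, 2)),
    timepoint = c("pre", "post", "pre", "post", "pre", "pre", "post"),
    response = rep(c("responder", "non-responder", "responder", "unknown"),
                   c(2, 2, 1, 2)),
    stringsAsFactors = FALSE)
  if (!is.null(clin_extra)) clin <- rbind(clin, clin_extra)
  ef <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  cf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(data.frame(gene = genes, expr, check.names = FALSE), ef,
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(clin, cf, sep = "\t", row.names = FALSE, quote = FALSE)
  list(expr = ef, clin = cf, mat = expr)
}

test_that("cohort assembly keeps complete pairs and drops unknown response", {
  fx <- write_cohort_fixture()
  msgs <- capture_messages(co <- read_cohort_tables(fx$expr, fx$clin))
  # patient c lacks a post sample, patient d has unknown response
  expect_identical(co$patients, c("a", "b"))
  expect_identical(unname(co$response), c("responder", "non-responder"))
  expect_true(any(grepl("unknown response", msgs)))
  expect_true(any(grepl("lacking a pre or post", msgs)))
  expect_equal(co$pre[, "a"], fx$mat[, "a_pre"])
  expect_equal(co$post[, "b"], fx$mat[, "b_post"])
})

test_that("duplicate biopsies error without the merge directive, average with it", {
  extra <- data.frame(sample_id = "a_pre2", patient_id = "a",
                      timepoint = "pre", response = "responder",
                      stringsAsFactors = FALSE)
  genes <- sprintf("g%d", 1:4)
  samples <- c("a_pre", "a_pre2", "a_post", "b_pre", "b_post")
  expr <- matrix(seq_len(20), nrow = 4, dimnames = list(genes, samples))
  clin <- data.frame(
    sample_id = samples, patient_id = c("a", "a", "a", "b", "b"),
    timepoint = c("pre", "pre", "post", "pre", "post"),
    response = c(rep("responder", 3), rep("non-responder", 2)),
    stringsAsFactors = FALSE)
  ef <- withr::local_tempfile(fileext = ".tsv")
  cf <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = genes, expr, check.names = FALSE), ef,
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(clin, cf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_cohort_tables(ef, cf), "multiple samples")
  co <- read_cohort_tables(ef, cf, merge_multiple_biopsies = TRUE)
  expect_equal(co$pre[, "a"], rowMeans(expr[, c("a_pre", "a_pre2")]))
})

test_that("pre/post files with mismatched gene lists are intersected", {
  genes1 <- c("g1", "g2", "g3")
  genes2 <- c("g2", "g3", "g4")
  pre <- matrix(1:6, 3, dimnames = list(genes1, c("a_pre", "b_pre")))
  post <- matrix(7:12, 3, dimnames = list(genes2, c("a_post", "b_post")))
  clin <- data.frame(sample_id = c("a_pre", "b_pre", "a_post", "b_post"),
                     patient_id = c("a", "b", "a", "b"),
                     timepoint = c("pre", "pre", "post", "post"),
                     response = c("responder", "non-responder",
                                  "responder", "non-responder"),
                     stringsAsFactors = FALSE)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  cf <- withr::local_tempfile()
  write.table(data.frame(gene = genes1, pre, check.names = FALSE), f1,
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(gene = genes2, post, check.names = FALSE), f2,
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(clin, cf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_message(co <- read_cohort_tables(c(f1, f2), cf), "intersection")
  expect_identical(rownames(co$pre), c("g2", "g3"))
})

test_that("perturbation filtering: inclusive TAS, stable gene-space projection", {
  mat <- matrix(rnorm(12), 4, 3,
                dimnames = list(c("g1", "g2", "g3", "g4"),
                                c("s1", "s2", "s3")))
  meta <- make_meta(3, tas = c(0.3, 0.4, 0.5))
  out <- suppressMessages(
    filter_perturbations(mat, meta, min_tas = 0.4,
                         gene_space = c("g3", "g1", "gX")))
  expect_identical(colnames(out$matrix), c("s2", "s3"))  # 0.4 kept: inclusive
  expect_identical(rownames(out$matrix), c("g3", "g1"))  # gene_space order
  # idempotent
  again <- suppressMessages(
    filter_perturbations(out$matrix, out$metadata, min_tas = 0.4,
                         gene_space = c("g3", "g1", "gX")))
  expect_identical(again$matrix, out$matrix)
  expect_identical(again$metadata, out$metadata)
  # min_tas = 0 keeps everything
  all_kept <- suppressMessages(
    filter_perturbations(mat, meta, min_tas = 0, gene_space = rownames(mat)))
  expect_identical(dim(all_kept$matrix), dim(mat))
  expect_error(
    suppressMessages(filter_perturbations(mat, meta, min_tas = 1,
                                          gene_space = "g1")),
    "review")
})
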