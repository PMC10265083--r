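test_that("cell_matrix validates symbols, counts and flags", {
  m <- small_counts()
  expect_s3_class(m, "cell_matrix")
  expect_true(m$gene_flags["MT-CO1", "mitochondrial"])
  expect_true(all(m$gene_flags[c("RPS4", "RPL9"), "ribosomal"]))
  expect_false(m$gene_flags["G001", "ribosomal"])
  expect_error(cell_matrix(matrix(-1, 1, 1, dimnames = list("A", "c1"))),
               "negative")
  counts <- matrix(1, 2, 1, dimnames = list(c("a1", "A1"), "c1"))
  expect_error(cell_matrix(counts), "duplicate gene symbols")
})

test_that("MTX fixture round-trips through write_fixture/load_counts", {
  d <- generate_dataset(sim_config(
    n_donors_per_group = c(NC = 1, ClassI = 1, ClassII = 1, ClassIII = 1,
                           ClassIV = 1),
    cells_per_donor = 60, seed = 11L))
  dir <- withr::local_tempdir()
  manifest <- write_fixture(d$matrix, d$truth, dir)
  re <- load_counts(dir, format = "mtx")
  expect_equal(as.matrix(re$counts), as.matrix(d$matrix$counts))
  expect_equal(re$cell_meta$donor, d$matrix$cell_meta$donor)
  expect_equal(manifest$n_cells, ncol(d$matrix$counts))
  # 300 cells = one line per cell in cells.tsv (plus header)
  expect_equal(length(readLines(file.path(dir, "cells.tsv"))) - 1L,
               5 * 60)
})

test_that("dense TSV loader matches the file cell-by-cell", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "toy.tsv")
  writeLines(c("gene\tc1\tc2", "A\t1\t2", "B\t0\t5", "C\t3\t0"), f)
  m <- load_counts(f, format = "tsv")
  expect_equal(unname(as.matrix(m$counts)),
               matrix(c(1, 0, 3, 2, 5, 0), 3, 2))
})

test_that("qc_filter applies strict boundaries and is idempotent", {
  # three cells straddling the thresholds; 2500-gene toy universe
  ng <- 2500
  counts <- matrix(0L, ng, 3,
                   dimnames = list(sprintf("G%04d", 1:ng), c("a", "b", "c")))
  counts[1:2000, 1] <- 10L       # exactly 2000 genes, 20000 transcripts
  counts[1:2001, 2] <- 5L        # 2001 genes, 10005 transcripts
  counts[1:2001, 2][1] <- 1L     # -> 10001 transcripts
  counts[1:2100, 3] <- 4L        # 2100 genes, 8400 transcripts
  m <- cell_matrix(counts)
  res <- qc_filter(m)
  expect_equal(res$matrix$cell_ids, "b")
  expect_setequal(res$report$cell_id, c("a", "c"))
  expect_match(res$report$reason[res$report$cell_id == "a"], "low_genes")
  expect_match(res$report$reason[res$report$cell_id == "c"], "low_transcripts")
  again <- qc_filter(res$matrix)
  expect_equal(again$matrix$cell_ids, res$matrix$cell_ids)
  expect_equal(nrow(again$report), 0)
})

test_that("qc_filter retains exactly the independently recounted set", {
  m <- sim_fixture()$matrix
  res <- qc_filter(m, min_genes = 500, min_transcripts = 15000)
  dense <- as.matrix(m$counts)
  recount <- colnames(dense)[colSums(dense > 0) > 500 &
                               colSums(dense) > 15000]
  expect_setequal(res$matrix$cell_ids, recount)
})

test_that("normalization hits the log2(TPM/10+1) contract", {
  counts <- matrix(c(90, 10, 1, 99999), 2, 2,
                   dimnames = list(c("A", "B"), c("c1", "c2")))
  nm <- normalize_counts(cell_matrix(counts), exclude = character())
  # count 90 of 100 -> TPM 900000 -> log2(90001)
  expect_equal(nm$values["A", "c1"], log2(9e5 / 10 + 1))
  expect_equal(nm$values["A", "c1"], log2(90001))
  # TPM 10 -> value 1; TPM 0 stays 0
  expect_equal(nm$values["A", "c2"], 1)
  zero <- matrix(c(0, 50), 2, 1, dimnames = list(c("A", "B"), "c1"))
  expect_equal(normalize_counts(cell_matrix(zero),
                                exclude = character())$values["A", 1], 0)
})

test_that("per-cell TPM sums to 1e6 and ribo/mito are excluded first", {
  m <- small_counts()
  nm <- normalize_counts(m)
  expect_false(any(c("MT-CO1", "RPS4", "RPL9") %in% rownames(nm$values)))
  expect_setequal(nm$excluded_genes, c("MT-CO1", "RPS4", "RPL9"))
  tpm <- (2^nm$values - 1) * 10
  expect_equal(colSums(tpm), setNames(rep(1e6, ncol(tpm)), colnames(tpm)),
               tolerance = 1e-6)
  # a cell left with zero counts after exclusion is an error naming it
  counts <- matrix(c(5, 0), 2, 1, dimnames = list(c("MT-CO1", "B"), "bad"))
  expect_error(normalize_counts(cell_matrix(counts)), "bad")
})

test_that("gene_set_zscore matches hand-computed z-scores", {
  v <- matrix(c(0, 2), 1, 2, dimnames = list("A", c("c1", "c2")))
  zs <- gene_set_zscore(toy_norm(v), gene_set("s", "A"))
  expect_equal(unname(zs$score), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # cell sitting at the per-gene mean scores 0
  v2 <- rbind(A = c(0, 1, 2), B = c(4, 2, 0))
  colnames(v2) <- c("c1", "c2", "c3")
  zs2 <- gene_set_zscore(toy_norm(v2), gene_set("s", c("A", "B")))
  expect_equal(unname(zs2$score["c2"]), 0)
  expect_error(gene_set_zscore(toy_norm(v2), gene_set("s", "ZZZ")),
               "no genes")
  # zero-variance genes are dropped with a warning, not scored
  v3 <- rbind(A = c(0, 2), B = c(1, 1))
  colnames(v3) <- c("c1", "c2")
  expect_warning(zs3 <- gene_set_zscore(toy_norm(v3),
                                        gene_set("s", c("A", "B"))),
                 "zero-variance")
  expect_equal(zs3$n_genes_used, 1)
})

test_that("full-universe z-scores average to zero across cells", {
  set.seed(5)
  v <- matrix(rlnorm(50 * 20), 50, 20)
  zs <- gene_set_zscore(toy_norm(v), gene_set("all", rownames(toy_norm(v)$values)))
  expect_equal(mean(zs$score), 0, tolerance = 1e-9)
})

test_that("wilcoxon exact branch equals brute-force enumeration", {
  expect_equal(wilcoxon_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(wilcoxon_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1000, n1); y <- sample(setdiff(1:1000, x), n2)
    mine <- wilcoxon_test(x, y)
    expect_equal(mine$method, "exact")
    # independent oracle: enumerate group-1 rank subsets directly
    r <- rank(c(x, y)); u_obs <- sum(r[1:n1]) - n1 * (n1 + 1) / 2
    all_u <- apply(combn(n1 + n2, n1), 2,
                   function(ix) sum(seq_len(n1 + n2)[ix]) - n1 * (n1 + 1) / 2)
    oracle <- min(1, 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs)))
    expect_equal(mine$p_value, oracle)
  }
})

test_that("wilcoxon approximation is calibrated under the null", {
  set.seed(2024)
  p <- replicate(2000, wilcoxon_test(rnorm(20), rnorm(20))$p_value)
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("chi-square matches the textbook Pearson formula", {
  r <- chisq_test(matrix(10, 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- chisq_test(rbind(c(20, 10), c(10, 20)))
  expect_equal(r2$statistic, 60 * 300^2 / 810000, tolerance = 1e-4)
  expect_equal(r2$statistic, 6.6667, tolerance = 1e-4)
  set.seed(8)
  for (i in 1:20) {
    tab <- matrix(rpois(12, 20) + 1, 3, 4)
    mine <- chisq_test(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, unname(ref$p.value))
  }
  expect_error(chisq_test(rbind(c(0, 0), c(1, 2))), "row")
})
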