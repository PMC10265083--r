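test_that("capacity score reproduces hand z-computation on a shifted toy", {
  set.seed(15)
  base <- matrix(rnorm(20 * 40, 5, 1), 20, 40)
  base[, 21:40] <- base[, 21:40] + 1   # group B shifted +1 on all genes
  rownames(base) <- sprintf("G%02d", 1:20)
  colnames(base) <- sprintf("c%02d", 1:40)
  nm <- toy_norm(base)
  groups <- rep(c("A", "B"), each = 20)
  cap <- spermatogenesis_score(nm, gene_set("s", rownames(base),
                                            "spermatogenesis"),
                               seq_len(40), groups)
  # hand z-scores over the pooled cells
  z <- t(apply(base, 1, function(x) (x - mean(x)) / sd(x)))
  hand <- colMeans(z)
  expect_equal(unname(cap$score), unname(hand))
  expect_equal(cap$summary$median[cap$summary$group == "B"],
               median(hand[21:40]))
  # a cell at every gene's mean scores 0
  vm <- cbind(base[, 1:2], at_mean = rowMeans(base[, 1:2]))
  cm <- spermatogenesis_score(toy_norm(vm), gene_set("s", rownames(base)),
                              1:3, c("A", "A", "B"))
  expect_equal(unname(cm$score[3]), 0, tolerance = 1e-12)
  # degenerate constant input errors after the zero-variance drop
  vc <- matrix(2, 5, 4, dimnames = list(sprintf("G%02d", 1:5),
                                        sprintf("c%d", 1:4)))
  expect_error(suppressWarnings(
    spermatogenesis_score(toy_norm(vc), gene_set("s", rownames(vc)),
                          1:4, rep("A", 4))), "zero variance")
})

test_that("groups are ranked by descending median with pairwise tests", {
  set.seed(16)
  sc <- c(rnorm(30, 2), rnorm(30, 1), rnorm(30, 0))
  cap <- structure(list(
    score = setNames(sc, sprintf("c%02d", seq_along(sc))),
    groups = rep(c("hi", "mid", "lo"), each = 30),
    summary = do.call(rbind, lapply(c("hi", "mid", "lo"), function(g)
      data.frame(group = g, n = 30,
                 median = median(sc[rep(c("hi", "mid", "lo"),
                                        each = 30) == g]),
                 q25 = 0, q75 = 0))),
    ranking = NULL), class = "capacity_result")
  r <- rank_groups(cap)
  expect_equal(r$ranking, c("hi", "mid", "lo"))
  expect_equal(unname(r$severity_rank[c("hi", "lo")]), c(1L, 3L))
  expect_false(r$ties_noted)
  expect_equal(nrow(r$pairwise), 3)
  # identical groups tie with p = 1
  cap2 <- structure(list(
    score = setNames(rep(c(1, 2), 10), sprintf("c%02d", 1:20)),
    groups = rep(c("A", "B"), each = 10),
    summary = data.frame(group = c("A", "B"), n = 10,
                         median = c(1.5, 1.5), q25 = 0, q75 = 0),
    ranking = NULL), class = "capacity_result")
  # both groups carry the identical {1,2} distribution
  r2 <- rank_groups(cap2)
  expect_true(r2$ties_noted)
  expect_equal(r2$pairwise$p_value, 1, tolerance = 0.05)
})

test_that("planted severity order is recovered on the default atlas", {
  d <- sim_fixture()
  germ <- which(germ_mask(d))
  cap <- spermatogenesis_score(
    d$norm, gene_set("sperm", d$truth$program_genes, "spermatogenesis"),
    germ, d$truth$cells$group[germ])
  cap <- rank_groups(cap)
  expect_equal(cap$ranking, names(sort(d$truth$severity_rank)))
})

test_that("Spearman trends match hand examples and monotone invariance", {
  # 5 donors, one swapped pair: rho = 0.9
  v <- matrix(0, 2, 10, dimnames = list(c("SWAP", "DEC"),
                                        sprintf("c%02d", 1:10)))
  means_swap <- c(1, 2, 3, 5, 4)
  means_dec <- c(5, 4, 3, 2, 1)
  for (i in 1:5) {
    v["SWAP", (2 * i - 1):(2 * i)] <- means_swap[i]
    v["DEC", (2 * i - 1):(2 * i)] <- means_dec[i]
  }
  # jitter within donors so cells vary but donor means are exact
  v["SWAP", seq(1, 9, 2)] <- v["SWAP", seq(1, 9, 2)] + 0.1
  v["SWAP", seq(2, 10, 2)] <- v["SWAP", seq(2, 10, 2)] - 0.1
  donors <- rep(sprintf("d%d", 1:5), each = 2)
  groups <- rep(sprintf("g%d", 1:5), each = 2)
  sev <- setNames(1:5, sprintf("g%d", 1:5))
  tr <- trend_correlations(toy_norm(v), sev, 1:10, donors, groups)
  expect_equal(tr$rho[tr$gene == "SWAP"], 0.9)
  expect_equal(tr$rho[tr$gene == "DEC"], -1)
  # invariance under a strictly monotone transform of the ranks
  sev2 <- setNames(c(1, 10, 100, 1000, 10000), names(sev))
  tr2 <- trend_correlations(toy_norm(v), sev2, 1:10, donors, groups)
  expect_equal(tr$rho, tr2$rho)
  expect_equal(tr$p_value, tr2$p_value)
  expect_error(trend_correlations(toy_norm(v[, 1:6]), sev, 1:6,
                                  donors[1:6], groups[1:6]),
               "4 donors")
  # 4 donors collapsed onto 2 ranks is rejected too
  expect_error(trend_correlations(toy_norm(v[, 1:8]), sev, 1:8,
                                  donors[1:8],
                                  rep(c("g1", "g2"), each = 4)),
               "3 severity ranks")
})

test_that("planted trend genes rank by |rho| with AUROC >= 0.9", {
  d <- sim_fixture()
  germ <- which(germ_mask(d))
  tc <- d$truth$cells
  tr <- suppressMessages(trend_correlations(
    d$norm, d$truth$severity_rank, germ, tc$donor[germ], tc$group[germ]))
  lab <- tr$gene %in% d$truth$planted_trend_genes$gene
  r <- rank(abs(tr$rho))
  auc <- (mean(r[lab]) - (sum(lab) + 1) / 2) / sum(!lab)
  expect_gte(auc, 0.9)
})

test_that("trend modules separate archetypes and are deterministic", {
  # genes duplicated from two archetypes split perfectly at m = 2
  prof <- rbind(matrix(rep(c(1, 2, 3, 4, 5), 6), 6, 5, byrow = TRUE),
                matrix(rep(c(5, 4, 3, 2, 1), 6), 6, 5, byrow = TRUE))
  prof <- prof + matrix(rnorm(60, 0, 0.01), 12, 5)
  rownames(prof) <- sprintf("g%02d", 1:12)
  trends <- data.frame(gene = rownames(prof),
                       rho = rep(c(0.9, -0.9), each = 6),
                       p_value = 0.001, p_adjusted = 0.01,
                       module = NA_integer_)
  tm <- trend_modules(trends, prof, m = 2, seed = 4L)
  expect_equal(tm$module, rep(c(1L, 2L), each = 6))
  tm2 <- trend_modules(trends, prof, m = 2, seed = 4L)
  expect_identical(tm$module, tm2$module)
  expect_error(trend_modules(trends, prof[c(1, 1, 1), ], m = 5), "distinct")
})

test_that("end modules capture the planted monotone genes", {
  d <- sim_fixture()
  germ <- which(germ_mask(d))
  tc <- d$truth$cells
  tr <- suppressMessages(trend_correlations(
    d$norm, d$truth$severity_rank, germ, tc$donor[germ], tc$group[germ]))
  gp <- group_mean_profiles(d$norm, germ, tc$group[germ],
                            group_order = names(sort(d$truth$severity_rank)))
  tm <- trend_modules(tr, gp, m = 5, seed = 1L)
  planted <- d$truth$planted_trend_genes
  up <- planted$gene[planted$slope > 0]
  dn <- planted$gene[planted$slope < 0]
  expect_gte(mean(tm$module[match(up, tm$gene)] == 1, na.rm = TRUE), 0.9)
  expect_gte(mean(tm$module[match(dn, tm$gene)] == 5, na.rm = TRUE), 0.9)
})

test_that("external overlap is plain set arithmetic", {
  trends <- data.frame(gene = c("A", "B", "C", "D"),
                       rho = c(.9, .8, -.8, -.9), p_value = .01,
                       p_adjusted = .01, module = c(1L, 1L, 2L, 2L))
  ov <- external_overlap(trends, list(up = c("B", "C", "X"),
                                      down = c("Y", "Z")))
  expect_equal(ov$n_overlap[ov$module == 1 & ov$list_name == "up"], 1)
  expect_equal(ov$overlap[ov$module == 1 & ov$list_name == "up"], "B")
  expect_equal(ov$n_overlap[ov$list_name == "down"], c(0, 0))
  ident <- external_overlap(trends, list(all = c("A", "B")))
  expect_equal(ident$n_overlap[ident$module == 1], 2)
  expect_error(external_overlap(trends, list(bad = character())), "nonempty")
})
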