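test_that("lr_statistic is the mean of means with a strict 10% gate", {
  v <- rbind(LIG = c(2, 2, 2, 2, 0, 0, 0, 0),
             REC = c(0, 0, 0, 0, 4, 4, 4, 4))
  colnames(v) <- sprintf("c%d", 1:8)
  nm <- toy_norm(v)
  r <- lr_statistic(nm, "LIG", "REC", 1:4, 5:8)
  expect_false(r$gated)
  expect_equal(r$statistic, 3)               # (2 + 4) / 2
  expect_equal(r$pct_ligand, 1)
  # exactly 10% expressed is gated out (strict >)
  v2 <- rbind(LIG = c(5, rep(0, 9)), REC = rep(1, 10))
  colnames(v2) <- sprintf("c%d", 1:10)
  r2 <- lr_statistic(toy_norm(v2), "LIG", "REC", 1:10, 1:10)
  expect_true(r2$gated)
  expect_true(is.na(r2$statistic))
  # absent gene: gated out with a notice, not an error
  expect_message(r3 <- lr_statistic(nm, "NOPE", "REC", 1:4, 5:8),
                 "not detected")
  expect_true(r3$gated)
  expect_error(lr_statistic(nm, "LIG", "REC", integer(), 5:8), "empty")
})

test_that("gating and statistics are invariant to cell order", {
  set.seed(18)
  v <- matrix(rlnorm(20 * 60), 20, 60,
              dimnames = list(sprintf("G%02d", 1:20), sprintf("c%02d", 1:60)))
  nm <- toy_norm(v)
  s1 <- lr_statistic(nm, "G01", "G02", 1:30, 31:60)
  perm <- sample(30)
  s2 <- lr_statistic(nm, "G01", "G02", (1:30)[perm], (31:60)[rev(seq_len(30))])
  expect_equal(s1$statistic, s2$statistic)
  expect_equal(s1$pct_ligand, s2$pct_ligand)
})

test_that("permutation p-values live on the 1/n_perm grid and are seeded", {
  set.seed(19)
  v <- matrix(rlnorm(30 * 80), 30, 80,
              dimnames = list(sprintf("G%02d", 1:30), sprintf("c%02d", 1:80)))
  nm <- toy_norm(v)
  types <- rep(c("A", "B"), each = 40)
  pairs <- data.frame(pair_id = c("p1", "p2"), ligand = c("G01", "G03"),
                      receptor = c("G02", "G04"))
  r1 <- lr_permutation_test(nm, pairs, types, n_perm = 100, seed = 5L)
  r2 <- lr_permutation_test(nm, pairs, types, n_perm = 100, seed = 5L)
  expect_identical(r1$p_value, r2$p_value)
  expect_true(all(abs(r1$p_value * 100 - round(r1$p_value * 100)) < 1e-9))
  # an observed statistic above every permuted value gives p = 0
  vb <- v
  vb["G01", types == "A"] <- vb["G01", types == "A"] + 50
  vb["G02", types == "B"] <- vb["G02", types == "B"] + 50
  rb <- lr_permutation_test(toy_norm(vb), pairs[1, ], types,
                            type_pairs = data.frame(sender_type = "A",
                                                    receiver_type = "B"),
                            n_perm = 100, seed = 5L)
  expect_equal(rb$p_value, 0)
  expect_true(rb$significant)
  # smoothed variant never returns 0
  rs <- lr_permutation_test(toy_norm(vb), pairs[1, ], types,
                            type_pairs = data.frame(sender_type = "A",
                                                    receiver_type = "B"),
                            n_perm = 100, seed = 5L, smooth = TRUE)
  expect_equal(rs$p_value, 1 / 101)
})

test_that("label-shuffled null keeps the significant fraction near alpha", {
  set.seed(20)
  ng <- 400; nc <- 300
  v <- matrix(rlnorm(ng * nc), ng, nc,
              dimnames = list(sprintf("G%04d", 1:ng), sprintf("c%03d", 1:nc)))
  nm <- toy_norm(v)
  types <- rep(c("A", "B"), each = nc / 2)
  pairs <- data.frame(pair_id = sprintf("p%03d", 1:200),
                      ligand = sample(rownames(v), 200, replace = TRUE),
                      receptor = sample(rownames(v), 200, replace = TRUE))
  res <- lr_permutation_test(nm, pairs, types,
                             type_pairs = data.frame(sender_type = "A",
                                                     receiver_type = "B"),
                             n_perm = 200, seed = 6L)
  frac <- mean(res$p_value[!res$gated] < 0.05)
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 / sum(!res$gated)) + 0.02)
})

test_that("planted ST->SSC ligand-receptor pairs are detected", {
  d <- sim_fixture()
  tc <- d$truth$cells
  nc_cells <- which(tc$group == "NC")
  nm <- norm_subset(d$norm, nc_cells)
  res <- suppressMessages(
    lr_permutation_test(nm, default_lr_pairs(), tc$true_type[nc_cells],
                        n_perm = 250, seed = 8L))
  planted <- d$truth$planted_lr_pairs
  for (i in seq_len(nrow(planted))) {
    row <- res[res$pair_id == planted$pair_id[i] &
                 res$sender_type == planted$sender_type[i] &
                 res$receiver_type == planted$receiver_type[i], ]
    expect_true(row$significant, info = planted$pair_id[i])
  }
})

test_that("network counts and deltas match manual tallies", {
  res <- data.frame(
    pair_id = c("a", "b", "c", "d"),
    ligand = "L", receptor = "R",
    sender_type = c("ST", "ST", "ST", "SSC"),
    receiver_type = c("SSC", "SSC", "SSC", "ST"),
    pct_ligand = 1, pct_receptor = 1, statistic = 1,
    p_value = c(0, 0, 0.01, 0.2), gated = FALSE, low_confidence = FALSE,
    significant = c(TRUE, TRUE, TRUE, FALSE))
  net <- build_network(res)
  expect_equal(net$counts["ST", "SSC"], 3L)
  expect_equal(net$counts["SSC", "ST"], 0L)
  expect_equal(sort(net$edges[["ST->SSC"]]), c("a", "b", "c"))
  expect_equal(net$node_strength[["ST"]], 3)
  # empty result: zero matrix
  empty <- build_network(res[res$significant == FALSE & FALSE, ],
                         types = c("ST", "SSC"))
  expect_true(all(empty$counts == 0))
  # delta: disease 5 vs reference 2 -> +3; gained/lost are set differences
  dis <- net
  ref <- build_network(res[2:4, ])
  dl <- delta_network(dis, ref)
  expect_equal(dl$delta["ST", "SSC"], 1L)
  expect_equal(dl$gained[["ST->SSC"]], "a")
  expect_null(dl$lost[["ST->SSC"]])
  expect_true(all(delta_network(net, net)$delta == 0))
})
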