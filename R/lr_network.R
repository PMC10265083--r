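#' Ligand-receptor interaction statistic for one pair and type pairing
#'
#' Expressed fraction is the share of cells with normalized value > 0. The
#' pair is gated out unless the ligand is expressed in strictly more than
#' `min_pct` of sender cells and the receptor in strictly more than
#' `min_pct` of receiver cells; a ligand or receptor absent from the matrix
#' is treated as not detected (gated out, not an error). The statistic is the
#' arithmetic mean of the ligand's mean expression over sender cells and the
#' receptor's mean over receiver cells, zeros included.
#'
#' @param norm a `norm_matrix`.
#' @param ligand,receptor gene symbols.
#' @param sender_cells,receiver_cells nonempty cell subsets.
#' @param min_pct strict expressed-fraction gate (default 0.10).
#' @return list: `statistic`, `pct_ligand`, `pct_receptor`, `gated`
#'   (TRUE when gated out; `statistic` is NA then).
#' @export
lr_statistic <- function(norm, ligand, receptor, sender_cells,
                         receiver_cells, min_pct = 0.10) {
  v <- norm$values
  ligand <- toupper(ligand); receptor <- toupper(receptor)
  if (!length(sender_cells) || !length(receiver_cells))
    stop("empty sender or receiver cell subset")
  if (!(ligand %in% rownames(v)) || !(receptor %in% rownames(v))) {
    message("pair ", ligand, "-", receptor, ": gene not detected, gated out")
    return(list(statistic = NA_real_, pct_ligand = NA_real_,
                pct_receptor = NA_real_, gated = TRUE))
  }
  lv <- v[ligand, sender_cells]
  rv <- v[receptor, receiver_cells]
  pct_l <- mean(lv > 0); pct_r <- mean(rv > 0)
  gated <- !(pct_l > min_pct && pct_r > min_pct)
  list(statistic = if (gated) NA_real_ else (mean(lv) + mean(rv)) / 2,
       pct_ligand = pct_l, pct_receptor = pct_r, gated = gated)
}

#' Permutation test for ligand-receptor interactions between cell types
#'
#' For every pair and every ordered (sender, receiver) type combination the
#' observed statistic is compared against a null built by shuffling the type
#' labels of all cells jointly; within one iteration the same permutation is
#' reused for every pair and type combination, preserving the marginal type
#' sizes. `p = #(null >= observed) / n_perm` (p = 0 allowed; set
#' `smooth = TRUE` for the (k+1)/(n+1) variant for downstream FDR use).
#' Significant iff the expression gates pass and p < alpha. Deterministic
#' given `seed`.
#'
#' @param norm a `norm_matrix`.
#' @param pairs data.frame(pair_id, ligand, receptor).
#' @param type_labels per-cell type labels (length ncol of the matrix).
#' @param type_pairs optional data.frame(sender_type, receiver_type) to
#'   restrict the combinations; default all ordered pairs of distinct labels
#'   plus self-pairs.
#' @param n_perm number of permutations (>= 100).
#' @param alpha significance level.
#' @param min_pct expression gate.
#' @param seed integer seed.
#' @param smooth use the +1-smoothed p-value.
#' @return data.frame of LR results: pair_id, ligand, receptor, sender_type,
#'   receiver_type, pct_ligand, pct_receptor, statistic, p_value, gated,
#'   low_confidence (either side < 3 cells), significant.
#' @export
lr_permutation_test <- function(norm, pairs, type_labels, type_pairs = NULL,
                                n_perm = 1000, alpha = 0.05, min_pct = 0.10,
                                seed = 1L, smooth = FALSE) {
  stopifnot(n_perm >= 100)
  v <- norm$values
  stopifnot(length(type_labels) == ncol(v))
  types <- sort(unique(type_labels))
  if (length(types) < 2) stop("need >= 2 cell types")
  if (is.null(type_pairs))
    type_pairs <- expand.grid(sender_type = types, receiver_type = types,
                              stringsAsFactors = FALSE)
  pairs$ligand <- toupper(pairs$ligand)
  pairs$receptor <- toupper(pairs$receptor)
  detected <- pairs$ligand %in% rownames(v) & pairs$receptor %in% rownames(v)
  if (any(!detected))
    message(sum(!detected), " pair(s) with undetected ligand/receptor gated out")
  genes <- unique(c(pairs$ligand[detected], pairs$receptor[detected]))
  type_n <- table(factor(type_labels, levels = types))

  grid <- merge(pairs[detected, , drop = FALSE], type_pairs)
  # expand.grid-free cross join keeps row order by pair then type pairing
  grid <- grid[order(match(grid$pair_id, pairs$pair_id),
                     match(grid$sender_type, types),
                     match(grid$receiver_type, types)), , drop = FALSE]
  rownames(grid) <- NULL

  sub <- v[genes, , drop = FALSE]
  f <- factor(type_labels, levels = types)
  grp_mean <- function(fac) {
    s <- rowsum(t(sub), fac)                 # types x genes sums
    s / as.vector(table(fac))
  }
  obs_means <- grp_mean(f)
  pct <- rowsum(t(sub > 0) + 0, f) / as.vector(table(f))

  li <- match(grid$ligand, genes); ri <- match(grid$receptor, genes)
  si <- match(grid$sender_type, types); ti <- match(grid$receiver_type, types)
  obs <- (obs_means[cbind(si, li)] + obs_means[cbind(ti, ri)]) / 2
  pct_l <- pct[cbind(si, li)]
  pct_r <- pct[cbind(ti, ri)]
  gated <- !(pct_l > min_pct & pct_r > min_pct)

  set.seed(seed)
  exceed <- numeric(nrow(grid))
  for (it in seq_len(n_perm)) {
    pf <- f[sample.int(length(f))]
    pm <- grp_mean(pf)
    null_stat <- (pm[cbind(si, li)] + pm[cbind(ti, ri)]) / 2
    exceed <- exceed + (null_stat >= obs)
  }
  p <- if (smooth) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  low_conf <- type_n[grid$sender_type] < 3 | type_n[grid$receiver_type] < 3

  res <- data.frame(grid[c("pair_id", "ligand", "receptor",
                           "sender_type", "receiver_type")],
                    pct_ligand = pct_l, pct_receptor = pct_r,
                    statistic = ifelse(gated, NA_real_, obs),
                    p_value = p, gated = gated,
                    low_confidence = as.vector(low_conf),
                    significant = !gated & p < alpha,
                    stringsAsFactors = FALSE)
  # undetected pairs appear as fully gated rows for every type pairing
  if (any(!detected)) {
    und <- merge(pairs[!detected, , drop = FALSE], type_pairs)
    und <- data.frame(und[c("pair_id", "ligand", "receptor",
                            "sender_type", "receiver_type")],
                      pct_ligand = NA_real_, pct_receptor = NA_real_,
                      statistic = NA_real_, p_value = NA_real_, gated = TRUE,
                      low_confidence = FALSE, significant = FALSE,
                      stringsAsFactors = FALSE)
    res <- rbind(res, und)
  }
  rownames(res) <- NULL
  res
}

#' Build the directed interaction-count network
#'
#' @param results LR result table from [lr_permutation_test()].
#' @param types optional type universe for the matrix dimensions.
#' @return list of class `interaction_network`: `counts` (directed type x
#'   type matrix of significant interactions), `edges` (named list
#'   "sender->receiver" -> pair ids).
#' @export
build_network <- function(results, types = NULL) {
  if (is.null(types))
    types <- sort(unique(c(results$sender_type, results$receiver_type)))
  counts <- matrix(0L, length(types), length(types),
                   dimnames = list(sender = types, receiver = types))
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  edges <- list()
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      s <- sig$sender_type[i]; r <- sig$receiver_type[i]
      counts[s, r] <- counts[s, r] + 1L
      key <- paste0(s, "->", r)
      edges[[key]] <- c(edges[[key]], sig$pair_id[i])
    }
  }
  structure(list(counts = counts, edges = edges,
                 node_strength = rowSums(counts) + colSums(counts)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", sum(x$counts), "significant interactions over",
      nrow(x$counts), "cell types\n")
  invisible(x)
}

#' Signed delta network (disease minus reference)
#'
#' Types missing from one network are treated as zero rows/columns. The
#' per-edge gained/lost pair lists are plain set differences.
#'
#' @param disease,reference `interaction_network` objects.
#' @return list: `delta` (signed matrix), `gained`, `lost` (per-edge pair
#'   id lists).
#' @export
delta_network <- function(disease, reference) {
  types <- sort(unique(c(rownames(disease$counts), rownames(reference$counts))))
  pad <- function(net) {
    m <- matrix(0L, length(types), length(types),
                dimnames = list(sender = types, receiver = types))
    m[rownames(net$counts), colnames(net$counts)] <- net$counts
    m
  }
  d <- pad(disease); r <- pad(reference)
  keys <- unique(c(names(disease$edges), names(reference$edges)))
  gained <- list(); lost <- list()
  for (k in keys) {
    g <- setdiff(disease$edges[[k]], reference$edges[[k]])
    l <- setdiff(reference$edges[[k]], disease$edges[[k]])
    if (length(g)) gained[[k]] <- g
    if (length(l)) lost[[k]] <- l
  }
  list(delta = d - r, gained = gained, lost = lost)
}
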