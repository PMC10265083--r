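#' G1/S and G2/M phase scores per cell
#'
#' Each phase program is scored with [gene_set_zscore()] over the chosen cell
#' subset; the per-cell result carries both scores with the cycling call
#' still unset (see [call_cycling()]).
#'
#' @param norm a `norm_matrix`.
#' @param g1s,g2m phase [gene_set()]s (default the canonical 43/54-gene
#'   lists from [cycle_gene_sets()]).
#' @param cells optional cell subset.
#' @return data.frame: `cell_id`, `s_score`, `g2m_score`, `cycling` (NA).
#' @export
phase_scores <- function(norm, g1s = NULL, g2m = NULL, cells = NULL) {
  if (is.null(g1s) || is.null(g2m)) {
    cc <- cycle_gene_sets()
    if (is.null(g1s)) g1s <- cc$g1s
    if (is.null(g2m)) g2m <- cc$g2m
  }
  s <- gene_set_zscore(norm, g1s, cells = cells)
  m <- gene_set_zscore(norm, g2m, cells = cells)
  data.frame(cell_id = names(s$score), s_score = unname(s$score),
             g2m_score = unname(m$score), cycling = NA,
             stringsAsFactors = FALSE)
}

#' Call cycling cells against a matched random-gene-set null
#'
#' The activity criterion: a cell is cycling iff its larger phase score
#' strictly exceeds the `quantile` quantile of a null distribution built by
#' scoring `null_draws` random gene sets matched in size to each phase set
#' (scores pooled over draws and cells). This self-calibrating rule is used
#' because the underlying study never states its activity criterion.
#'
#' @param scores output of [phase_scores()].
#' @param norm the `norm_matrix` the scores came from.
#' @param g1s,g2m the phase sets used (sizes are matched after intersection
#'   with the matrix).
#' @param null_draws number of random sets per phase (>= 50).
#' @param quantile null quantile for the activity threshold.
#' @param cells the same cell subset used for `scores`.
#' @param seed integer; the call is deterministic given the seed.
#' @return `scores` with `cycling` set, plus attribute `threshold`.
#' @export
call_cycling <- function(scores, norm, g1s = NULL, g2m = NULL,
                         null_draws = 200, quantile = 0.99, cells = NULL,
                         seed = 1L) {
  stopifnot(null_draws >= 50)
  if (is.null(g1s) || is.null(g2m)) {
    cc <- cycle_gene_sets()
    if (is.null(g1s)) g1s <- cc$g1s
    if (is.null(g2m)) g2m <- cc$g2m
  }
  v <- norm$values
  if (!is.null(cells)) v <- v[, cells, drop = FALSE]
  pool <- rownames(v)
  sizes <- c(length(intersect(g1s$genes, pool)),
             length(intersect(g2m$genes, pool)))
  if (any(sizes == 0)) stop("phase set absent from matrix")
  if (length(pool) < max(sizes))
    stop("too few genes to draw size-matched random sets")
  set.seed(seed)
  null_scores <- vector("list", 2 * null_draws)
  k <- 0L
  for (i in seq_len(null_draws)) {
    for (sz in sizes) {
      gs <- sample(pool, sz)
      sc <- suppressWarnings(tryCatch(
        gene_set_zscore(norm, gene_set("null", gs), cells = cells)$score,
        error = function(e) NULL))
      if (!is.null(sc)) { k <- k + 1L; null_scores[[k]] <- sc }
    }
  }
  if (!k) stop("all random null sets degenerate")
  thr <- stats::quantile(unlist(null_scores[seq_len(k)]), probs = quantile,
                         names = FALSE)
  scores$cycling <- pmax(scores$s_score, scores$g2m_score) > thr
  attr(scores, "threshold") <- thr
  scores
}

#' Cycling-cell ratio per group with pairwise chi-square tests
#'
#' @param cycling logical per-cell cycling calls.
#' @param groups per-cell group labels.
#' @param reference reference group for the pairwise 2x2 tests.
#' @return list: `ratio` (named per group), `tests` (data.frame of group,
#'   statistic, p_value vs reference).
#' @export
active_ratio_compare <- function(cycling, groups, reference = "NC") {
  stopifnot(length(cycling) == length(groups))
  if (!reference %in% groups) stop("reference group '", reference,
                                   "' has no cells")
  tab <- table(groups)
  if (any(tab == 0)) stop("empty group")
  gl <- names(tab)
  ratio <- vapply(gl, function(g) mean(cycling[groups == g]), numeric(1))
  ref_c <- sum(cycling[groups == reference])
  ref_n <- sum(groups == reference)
  others <- setdiff(gl, reference)
  tests <- do.call(rbind, lapply(others, function(g) {
    gc <- sum(cycling[groups == g]); gn <- sum(groups == g)
    m <- rbind(c(gc, gn - gc), c(ref_c, ref_n - ref_c))
    tr <- if (any(colSums(m) == 0))
      list(statistic = 0, p_value = 1) else chisq_test(m)
    data.frame(group = g, ratio = gc / gn, statistic = tr$statistic,
               p_value = tr$p_value, stringsAsFactors = FALSE)
  }))
  list(ratio = ratio, reference = reference, tests = tests)
}
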