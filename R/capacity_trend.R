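#' Spermatogenesis capacity score
#'
#' The capacity score of a spermatogenic cell is the average z-score of a
#' curated spermatogenesis gene set (z computed per gene across the pooled
#' germ cells, sample sd). Group summaries use the median and IQR since the
#' score distributions are skewed.
#'
#' @param norm a `norm_matrix`.
#' @param set spermatogenesis [gene_set()].
#' @param germ_cells cell ids/indices of the spermatogenic cells.
#' @param groups per-germ-cell group labels (same order as `germ_cells`).
#' @return list of class `capacity_result`: `score` (named per cell),
#'   `groups`, `summary` (data.frame group, n, median, q25, q75), `ranking`
#'   (NULL until [rank_groups()]), `n_genes_used`.
#' @export
spermatogenesis_score <- function(norm, set, germ_cells, groups) {
  zs <- gene_set_zscore(norm, set, cells = germ_cells)
  stopifnot(length(groups) == length(zs$score))
  gl <- unique(groups)
  summ <- do.call(rbind, lapply(gl, function(g) {
    s <- zs$score[groups == g]
    data.frame(group = g, n = length(s), median = stats::median(s),
               q25 = stats::quantile(s, .25, names = FALSE),
               q75 = stats::quantile(s, .75, names = FALSE),
               stringsAsFactors = FALSE)
  }))
  structure(list(score = zs$score, groups = groups, summary = summ,
                 ranking = NULL, pairwise = NULL,
                 n_genes_used = zs$n_genes_used),
            class = "capacity_result")
}

#' Rank groups by capacity score
#'
#' Orders groups by descending median score (best capacity first) and
#' attaches all pairwise two-sided Wilcoxon tests. Severity rank is the
#' position in the ranking (best = 1). Ties in medians keep a total order
#' (alphabetical among tied groups) and are flagged.
#'
#' @param result a `capacity_result`.
#' @return the result with `ranking`, `severity_rank`, `pairwise` and
#'   `ties_noted` set.
#' @export
rank_groups <- function(result) {
  stopifnot(inherits(result, "capacity_result"))
  summ <- result$summary
  if (nrow(summ) < 2 || any(summ$n < 2))
    stop("need >= 2 groups with >= 2 cells each")
  ord <- order(-summ$median, summ$group)
  ranking <- summ$group[ord]
  ties <- anyDuplicated(summ$median) > 0
  gl <- ranking
  pw <- list(); k <- 0L
  for (i in seq_along(gl)) for (j in seq_along(gl)) if (i < j) {
    tr <- wilcoxon_test(result$score[result$groups == gl[i]],
                        result$score[result$groups == gl[j]])
    k <- k + 1L
    pw[[k]] <- data.frame(group1 = gl[i], group2 = gl[j],
                          statistic = tr$statistic, p_value = tr$p_value,
                          effect = tr$effect, stringsAsFactors = FALSE)
  }
  result$ranking <- ranking
  result$severity_rank <- stats::setNames(seq_along(ranking), ranking)
  result$pairwise <- do.call(rbind, pw)
  result$ties_noted <- ties
  result
}

#' @export
print.capacity_result <- function(x, ...) {
  cat("capacity_result over", length(x$score), "germ cells (",
      x$n_genes_used, "set genes )\n")
  print(x$summary)
  if (!is.null(x$ranking))
    cat("ranking (best -> worst):", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Spearman trend correlations against severity rank
#'
#' For each gene, the Spearman correlation between its per-donor mean
#' expression in germ cells and the donor's group severity rank, with a
#' two-sided p-value and Benjamini-Hochberg adjustment over genes. Donor
#' means (not cells) are the correlation unit to avoid pseudoreplication.
#' Genes constant across donors have undefined rho and are excluded.
#'
#' @param norm a `norm_matrix`.
#' @param severity_rank named map group -> severity rank (from
#'   [rank_groups()] or planted truth).
#' @param germ_cells germ-cell ids/indices.
#' @param donors,groups per-germ-cell donor and group labels.
#' @return data.frame: gene, rho, p_value, p_adjusted (module unset).
#' @export
trend_correlations <- function(norm, severity_rank, germ_cells,
                               donors, groups) {
  v <- norm$values[, germ_cells, drop = FALSE]
  stopifnot(length(donors) == ncol(v), length(groups) == ncol(v))
  ids <- sort(unique(donors))
  if (length(ids) < 4) stop("need >= 4 donors")
  donor_rank <- vapply(ids, function(d)
    severity_rank[[groups[match(d, donors)]]], numeric(1))
  if (length(unique(donor_rank)) < 3)
    stop("donors span fewer than 3 severity ranks")
  dm <- vapply(ids, function(d) rowMeans(v[, donors == d, drop = FALSE]),
               numeric(nrow(v)))
  keep <- apply(dm, 1, function(x) stats::sd(x) > 0)
  if (any(!keep))
    message(sum(!keep), " gene(s) constant across donors excluded")
  dm <- dm[keep, , drop = FALSE]
  rho <- as.numeric(stats::cor(t(dm), donor_rank, method = "spearman"))
  pv <- vapply(seq_len(nrow(dm)), function(i)
    suppressWarnings(stats::cor.test(dm[i, ], donor_rank,
                                     method = "spearman"))$p.value,
    numeric(1))
  data.frame(gene = rownames(dm), rho = rho, p_value = pv,
             p_adjusted = stats::p.adjust(pv, method = "BH"),
             module = NA_integer_, stringsAsFactors = FALSE)
}

#' Assign trend genes to monotone modules
#'
#' K-means (25 restarts, seeded) on each gene's severity-ordered group-mean
#' profile standardized to zero mean and unit variance. Modules are
#' renumbered so Module 1 has the most positive mean rho (expression rises
#' as capacity falls) and Module `m` the most negative (expression falls).
#'
#' @param trends output of [trend_correlations()].
#' @param group_profiles gene x group matrix of mean expression with columns
#'   in severity order (built by [group_mean_profiles()]).
#' @param m number of modules.
#' @param seed integer seed.
#' @return `trends` with the `module` column set for profiled genes.
#' @export
trend_modules <- function(trends, group_profiles, m = 5, seed = 1L) {
  genes <- intersect(trends$gene, rownames(group_profiles))
  prof <- group_profiles[genes, , drop = FALSE]
  sd_ <- apply(prof, 1, stats::sd)
  genes <- genes[sd_ > 0]
  prof <- prof[genes, , drop = FALSE]
  if (nrow(unique(prof)) < m)
    stop("fewer distinct profiles (", nrow(unique(prof)), ") than modules (",
         m, ")")
  z <- t(scale(t(prof)))
  set.seed(seed)
  km <- stats::kmeans(z, centers = m, nstart = 25, iter.max = 100)
  rho <- trends$rho[match(genes, trends$gene)]
  mean_rho <- vapply(seq_len(m), function(k) mean(rho[km$cluster == k]),
                     numeric(1))
  relabel <- match(seq_len(m), order(mean_rho, decreasing = TRUE))
  trends$module <- NA_integer_
  trends$module[match(genes, trends$gene)] <- relabel[km$cluster]
  trends
}

#' Gene x group mean-expression profiles over germ cells
#'
#' @param norm a `norm_matrix`.
#' @param germ_cells germ-cell subset.
#' @param groups per-germ-cell group labels.
#' @param group_order column order (typically the severity-ordered ranking).
#' @export
group_mean_profiles <- function(norm, germ_cells, groups,
                                group_order = sort(unique(groups))) {
  v <- norm$values[, germ_cells, drop = FALSE]
  vapply(group_order, function(g) rowMeans(v[, groups == g, drop = FALSE]),
         numeric(nrow(v)))
}

#' Intersect trend modules with external disease gene lists
#'
#' Pure set arithmetic (no inference): for each (module, external list) the
#' intersection size and symbols, used to ask whether capacity-predictor
#' modules recur in other testicular diseases.
#'
#' @param trends module-annotated trend table.
#' @param external_lists named list of character gene vectors.
#' @return data.frame: module, list_name, n_module, n_list, n_overlap,
#'   overlap (comma-joined symbols).
#' @export
external_overlap <- function(trends, external_lists) {
  if (!length(external_lists) || any(lengths(external_lists) == 0))
    stop("external lists must be nonempty")
  mods <- sort(unique(trends$module[!is.na(trends$module)]))
  out <- list(); k <- 0L
  for (md in mods) {
    mg <- trends$gene[!is.na(trends$module) & trends$module == md]
    for (nm in names(external_lists)) {
      ext <- toupper(external_lists[[nm]])
      ov <- intersect(mg, ext)
      k <- k + 1L
      out[[k]] <- data.frame(module = md, list_name = nm,
                             n_module = length(mg), n_list = length(ext),
                             n_overlap = length(ov),
                             overlap = paste(sort(ov), collapse = ","),
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
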