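#' Per-cell-type differential expression against the reference group
#'
#' For each disease class and each cell type present with at least
#' `min_cells` cells on both sides, genes pass to testing only if their
#' expressed fraction reaches `min_pct` on at least one side and the absolute
#' mean difference on the log2(TPM/10+1) scale reaches `logfc_threshold`
#' (the legacy `thresh.use = 2` gate). Passing genes get a two-sided Wilcoxon
#' rank-sum p-value, Bonferroni-adjusted over the genes tested within each
#' (class, cell type) comparison; records with adjusted p below `alpha` are
#' emitted.
#'
#' @param norm a `norm_matrix`.
#' @param class_labels per-cell class/group labels (reference label included).
#' @param cell_types per-cell type labels.
#' @param reference reference label (controls).
#' @param logfc_threshold absolute mean-difference gate on the log2 scale.
#' @param min_pct expressed-fraction gate.
#' @param alpha adjusted-p cutoff for emitted records.
#' @param min_cells minimum cells per side.
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @return data.frame of DEG records: gene, cell_type, class_label,
#'   direction (up/down: class vs reference), effect, pct1, pct2, p_value,
#'   p_adjusted.
#' @export
deg_per_celltype <- function(norm, class_labels, cell_types, reference,
                             logfc_threshold = 2, min_pct = 0.25,
                             alpha = 0.05, min_cells = 3,
                             adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  v <- norm$values
  stopifnot(length(class_labels) == ncol(v), length(cell_types) == ncol(v))
  classes <- setdiff(unique(class_labels), c(reference, "unassigned", NA))
  out <- list(); oi <- 0L
  for (cl in classes) {
    for (ty in setdiff(unique(cell_types), c("unassigned", NA))) {
      i1 <- which(class_labels == cl & cell_types == ty)
      i2 <- which(class_labels == reference & cell_types == ty)
      if (length(i1) < min_cells || length(i2) < min_cells) {
        message("skipping ", cl, " / ", ty, ": too few cells (",
                length(i1), " vs ", length(i2), ")")
        next
      }
      v1 <- v[, i1, drop = FALSE]; v2 <- v[, i2, drop = FALSE]
      m1 <- rowMeans(v1); m2 <- rowMeans(v2)
      p1 <- rowMeans(v1 > 0); p2 <- rowMeans(v2 > 0)
      eff <- m1 - m2
      test_genes <- which(pmax(p1, p2) >= min_pct &
                            abs(eff) >= logfc_threshold &
                            (p1 > 0 | p2 > 0))
      if (!length(test_genes)) next
      pv <- vapply(test_genes, function(gi)
        wilcoxon_test(v1[gi, ], v2[gi, ])$p_value, numeric(1))
      padj <- stats::p.adjust(pv, method = adjust)
      keep <- padj < alpha
      if (!any(keep)) next
      oi <- oi + 1L
      out[[oi]] <- data.frame(
        gene = rownames(v)[test_genes[keep]],
        cell_type = ty, class_label = cl,
        direction = ifelse(eff[test_genes[keep]] > 0, "up", "down"),
        effect = unname(eff[test_genes[keep]]),
        pct1 = unname(p1[test_genes[keep]]),
        pct2 = unname(p2[test_genes[keep]]),
        p_value = pv[keep], p_adjusted = padj[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), cell_type = character(),
                      class_label = character(), direction = character(),
                      effect = numeric(), pct1 = numeric(), pct2 = numeric(),
                      p_value = numeric(), p_adjusted = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default germ-stage lists per class for the frequency screen
#'
#' Class I covers all nine germ stages; the pachytene-arrest classes
#' (II-IV) use only the stages up to pachytene, so the absent D, SPC7 and RS
#' stages (RS exclusion is explicit in the source analysis) never block
#' qualification.
#' @param classes class labels.
#' @param arrest named map class -> last germ stage present.
#' @export
default_germ_types_by_class <- function(
    classes = c("ClassI", "ClassII", "ClassIII", "ClassIV"),
    arrest = c(ClassI = "RS", ClassII = "P", ClassIII = "P", ClassIV = "P")) {
  stages <- germ_stage_order()
  out <- lapply(classes, function(cl)
    stages[seq_len(match(arrest[[cl]], stages))])
  stats::setNames(out, classes)
}

#' Cross-class DEG frequency screen
#'
#' A gene qualifies in a class iff it carries a DEG record of the requested
#' direction in *every* listed germ stage of that class; its frequency is the
#' number of qualifying classes (0..number of classes). This is the screen
#' that nominates candidate pathogenic genes shared across arrest classes.
#'
#' @param records DEG records from [deg_per_celltype()].
#' @param germ_types_by_class named list class -> required cell types.
#' @param direction `"down"` (default) or `"up"`.
#' @return data.frame sorted by frequency (desc) then gene: gene, frequency,
#'   one logical qualification column per class.
#' @export
frequency_screen <- function(records,
                             germ_types_by_class = default_germ_types_by_class(),
                             direction = "down") {
  if (!length(germ_types_by_class)) stop("no classes given")
  empties <- lengths(germ_types_by_class) == 0
  if (any(empties))
    stop("empty cell-type list for class ",
         names(germ_types_by_class)[empties][1])
  rec <- records[records$direction == direction, , drop = FALSE]
  genes <- sort(unique(rec$gene))
  classes <- names(germ_types_by_class)
  qual <- matrix(FALSE, length(genes), length(classes),
                 dimnames = list(genes, classes))
  for (cl in classes) {
    need <- germ_types_by_class[[cl]]
    rc <- rec[rec$class_label == cl & rec$cell_type %in% need, , drop = FALSE]
    if (!nrow(rc)) next
    cover <- tapply(rc$cell_type, rc$gene,
                    function(t) all(need %in% t))
    qual[names(cover)[cover], cl] <- TRUE
  }
  freq <- rowSums(qual)
  out <- data.frame(gene = genes, frequency = as.integer(freq),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(qual))
  out <- out[order(-out$frequency, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Frequency screen restricted to a fixed cell-type subset
#'
#' Same ALL-quantifier as [frequency_screen()] but every class must show the
#' gene in the same fixed subset of cell types (e.g. just SSC, to nominate
#' spermatogonial-stem-cell candidates).
#'
#' @param records DEG records.
#' @param cell_types nonempty character subset.
#' @param classes class labels screened.
#' @param direction `"down"` or `"up"`.
#' @export
celltype_subset_screen <- function(records, cell_types,
                                   classes = c("ClassI", "ClassII",
                                               "ClassIII", "ClassIV"),
                                   direction = "down") {
  if (!length(cell_types)) stop("empty cell-type subset")
  lists <- stats::setNames(rep(list(cell_types), length(classes)), classes)
  frequency_screen(records, lists, direction = direction)
}
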