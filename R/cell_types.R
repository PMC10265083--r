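#' Marker-panel cell typing
#'
#' Scores every cell against every cell-type marker panel with
#' [gene_set_zscore()] and assigns the argmax label. Cells whose margin
#' between the top two panel scores falls below `min_margin` (in z units) are
#' labelled `"unassigned"` rather than given a coin-flip call.
#'
#' @param norm a `norm_matrix`.
#' @param panels a [marker_panel_set()].
#' @param min_margin minimum top-two score margin for a confident call.
#' @return data.frame (one row per cell): `cell_id`, `label`, `top_score`,
#'   `margin`, plus one score column per panel.
#' @export
assign_types <- function(norm, panels = default_marker_panels(),
                         min_margin = 0.1) {
  stopifnot(inherits(norm, "norm_matrix"), inherits(panels, "marker_panel_set"))
  labels <- names(panels$panels)
  scores <- vapply(labels, function(lb) {
    p <- panels$panels[[lb]]
    if (!length(intersect(p$genes, rownames(norm$values))))
      stop("no marker genes present for panel '", lb, "'")
    gene_set_zscore(norm, p)$score
  }, numeric(ncol(norm$values)))
  ord <- t(apply(scores, 1, order, decreasing = TRUE))
  top <- labels[ord[, 1]]
  top_score <- scores[cbind(seq_len(nrow(scores)), ord[, 1])]
  second <- scores[cbind(seq_len(nrow(scores)), ord[, 2])]
  margin <- top_score - second
  label <- ifelse(margin < min_margin, "unassigned", top)
  out <- data.frame(cell_id = colnames(norm$values), label = label,
                    top_score = top_score, margin = margin,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(scores, check.names = FALSE))
}

#' Group x cell-type composition table
#'
#' @param labels per-cell type labels.
#' @param groups per-cell group labels (same length).
#' @param drop_unassigned drop cells labelled "unassigned".
#' @return integer matrix group x cell type.
#' @export
composition_table <- function(labels, groups, drop_unassigned = TRUE) {
  stopifnot(length(labels) == length(groups))
  if (drop_unassigned) {
    keep <- labels != "unassigned"
    labels <- labels[keep]; groups <- groups[keep]
  }
  unclass(table(group = groups, cell_type = labels))
}

#' Chi-square test of composition differences between groups
#'
#' Delegates to [chisq_test()] on the group x type count table, the test used
#' for cell-number-ratio comparisons between disease classes and controls.
#'
#' @param tab a composition table ([composition_table()]).
#' @return `test_result`.
#' @export
composition_test <- function(tab) chisq_test(tab)
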