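#' Per-donor pseudobulk profiles
#'
#' Averages the normalized values of each donor's cells, giving one
#' expression profile per donor for patient-level clustering.
#'
#' @param norm a `norm_matrix` whose `cell_meta` has a `donor` column.
#' @return list of class `donor_profiles`: `profiles` (gene x donor matrix,
#'   donors sorted by id), `n_cells` (named integer).
#' @export
pseudobulk <- function(norm) {
  stopifnot(inherits(norm, "norm_matrix"))
  donor <- norm$cell_meta$donor
  if (is.null(donor) || any(is.na(donor) | !nzchar(donor))) {
    bad <- which(is.na(donor) | !nzchar(donor))
    stop("cells without donor label: ",
         paste(utils::head(colnames(norm$values)[bad], 5), collapse = ", "))
  }
  ids <- sort(unique(donor))
  prof <- vapply(ids, function(d)
    rowMeans(norm$values[, donor == d, drop = FALSE]),
    numeric(nrow(norm$values)))
  structure(list(profiles = prof,
                 n_cells = stats::setNames(as.integer(table(donor)[ids]), ids)),
            class = "donor_profiles")
}

#' Hierarchical donor clustering into arrest classes
#'
#' Donors are clustered with average-linkage hierarchical clustering on
#' 1 - Pearson correlation over the top `n_var_genes` most variable genes of
#' the pseudobulk profiles, and the tree is cut into `k` groups. The group
#' holding the majority of the reference (control) donors is labelled
#' `ClassI` -- mirroring the definition of Class I as the patients that
#' co-cluster with normals; remaining groups are labelled `C2..Ck` in
#' dendrogram order and are meant to be relabelled downstream once capacity
#' ranking is available. Donors are processed in sorted-id order so the
#' result does not depend on input order.
#'
#' @param profiles a `donor_profiles` object.
#' @param k number of classes (>= 2).
#' @param reference_donors donor ids of the control group.
#' @param n_var_genes number of most-variable genes used for the distance.
#' @return list of class `class_assignment`: `classes` (named donor ->
#'   label), `k`, `hclust` (the merge record), `labels_by_cluster`.
#' @export
cluster_donors <- function(profiles, k = 5, reference_donors,
                           n_var_genes = 2000) {
  stopifnot(inherits(profiles, "donor_profiles"), k >= 2)
  prof <- profiles$profiles[, sort(colnames(profiles$profiles)), drop = FALSE]
  if (ncol(prof) < k)
    stop("k = ", k, " exceeds the number of donors (", ncol(prof), ")")
  v <- apply(prof, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(n_var_genes, nrow(prof)))]
  cors <- stats::cor(prof[top, , drop = FALSE])
  hc <- stats::hclust(stats::as.dist(1 - cors), method = "average")
  grp <- stats::cutree(hc, k = k)
  ref_grp <- grp[intersect(names(grp), reference_donors)]
  if (!length(ref_grp)) stop("no reference donors found among profiles")
  class1 <- as.integer(names(which.max(table(ref_grp))))
  # dendrogram (merge) order for the remaining clusters
  dend_order <- unique(grp[hc$order])
  others <- setdiff(dend_order, class1)
  lab <- character(k)
  lab[class1] <- "ClassI"
  lab[others] <- paste0("C", seq_along(others) + 1)
  structure(list(classes = stats::setNames(lab[grp], names(grp)),
                 k = k, hclust = hc,
                 labels_by_cluster = lab),
            class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  cat("class_assignment (k =", x$k, "):\n")
  print(table(x$classes))
  invisible(x)
}
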