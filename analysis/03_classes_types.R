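#!/usr/bin/env Rscript
# Donor-level stratification (hierarchical clustering of pseudobulk
# profiles) and marker-panel cell typing, compared against the planted
# truth; then the group x cell-type composition chi-square.

suppressPackageStartupMessages(library(spermatocap))

norm <- readRDS("results/norm.rds")
truth <- utils::read.delim("results/atlas/truth.tsv")
truth <- truth[match(colnames(norm$values), truth$cell_id), ]

pb <- pseudobulk(norm)
ref <- grep("^NC", colnames(pb$profiles), value = TRUE)
cl <- cluster_donors(pb, k = 5, reference_donors = ref)
print(cl)
truth_cls <- sub("_d.*$", "", names(cl$classes))
if (requireNamespace("mclust", quietly = TRUE))
  cat("ARI vs planted donor classes:",
      round(mclust::adjustedRandIndex(cl$classes, truth_cls), 3), "\n")
utils::write.table(
  data.frame(donor = names(cl$classes), class = unname(cl$classes),
             n_cells = pb$n_cells[names(cl$classes)]),
  "results/classes.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

typed <- suppressWarnings(assign_types(norm))
acc <- mean(typed$label == truth$true_type)
cat("Cell typing accuracy vs planted truth:", round(acc, 3),
    "(", sum(typed$label == "unassigned"), "unassigned )\n")
utils::write.table(typed[, c("cell_id", "label", "top_score", "margin")],
                   "results/cells_typed.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

tab <- composition_table(typed$label, truth$group)
ct <- composition_test(tab[, colSums(tab) > 0, drop = FALSE])
cat("Composition chi-square: statistic =", round(ct$statistic, 1),
    " df =", ct$df, " p =", format(ct$p_value, digits = 3), "\n")
utils::write.table(as.data.frame.matrix(tab), "results/composition.tsv",
                   sep = "\t", quote = FALSE)
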