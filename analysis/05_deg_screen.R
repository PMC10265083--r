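#!/usr/bin/env Rscript
# Per-cell-type Wilcoxon differential expression of each arrest class
# against NC (|mean log2 difference| >= 2, min.pct 0.25, Bonferroni), then
# the cross-class frequency screen nominating candidate pathogenic genes
# and the SSC-restricted screen.

suppressPackageStartupMessages(library(spermatocap))

norm <- readRDS("results/norm.rds")
truth <- utils::read.delim("results/atlas/truth.tsv")
truth <- truth[match(colnames(norm$values), truth$cell_id), ]

deg <- suppressMessages(
  deg_per_celltype(norm, truth$group, truth$true_type, reference = "NC"))
cat("DEG records:", nrow(deg), "(",
    sum(deg$direction == "down"), "down /", sum(deg$direction == "up"),
    "up )\n")
utils::write.table(deg, "results/deg.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

fr <- frequency_screen(deg)
cat("Top of the downregulated-gene frequency screen:\n")
print(head(fr[, c("gene", "frequency")], 12))
cat("LELP1 frequency:", fr$frequency[fr$gene == "LELP1"], "\n")
utils::write.table(fr, "results/frequency.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

ssc <- celltype_subset_screen(deg, "SSC")
cat("Genes down in SSC of all four classes:",
    sum(ssc$frequency == 4), "\n")
utils::write.table(ssc, "results/frequency_ssc.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
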