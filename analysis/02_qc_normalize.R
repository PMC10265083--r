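#!/usr/bin/env Rscript
# QC-filter and normalize the simulated atlas. The QC thresholds scale with
# the simulated library depth (the >2000-gene / >10000-transcript defaults
# are calibrated for full-depth human libraries, not the 2000-gene desk-scale
# universe simulated here).

suppressPackageStartupMessages(library(spermatocap))

mat <- load_counts("results/atlas", format = "mtx")
cat("Loaded", nrow(mat$counts), "genes x", ncol(mat$counts), "cells\n")

flt <- qc_filter(mat, min_genes = 500, min_transcripts = 15000)
cat("QC removed", nrow(flt$report), "cells; retained",
    ncol(flt$matrix$counts), "\n")
if (nrow(flt$report)) print(head(flt$report))
utils::write.table(flt$report, "results/qc_report.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

norm <- normalize_counts(flt$matrix)
cat("Normalized to log2(TPM/10+1);", length(norm$excluded_genes),
    "ribosomal/mitochondrial genes excluded before rescaling\n")
tpm <- colSums((2^norm$values - 1) * 10)
cat("Per-cell TPM totals: max |error| =",
    format(max(abs(tpm - 1e6)), digits = 3), "\n")
saveRDS(norm, "results/norm.rds")
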