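Package: spermatocap
Title: Spermatogenic-Capacity Analysis of Testicular Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for single-cell RNA-seq atlases of the human
    testis in nonobstructive azoospermia. Provides quality-control filtering and
    log2(TPM/10+1) normalization for 3'-tag count matrices, donor-level
    hierarchical stratification into spermatogenic arrest classes, marker-panel
    cell typing, G1/S and G2/M cell-cycle activity scoring with a matched
    random-gene-set null, a cross-class Wilcoxon differential-expression
    frequency screen for candidate pathogenic genes, gene-set z-score
    spermatogenesis-capacity scoring with monotone trend-module discovery, and
    permutation ligand-receptor interaction networks. A seeded synthetic
    testis-atlas generator with planted ground truth makes every stage testable
    without access to controlled human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Seurat,
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
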