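# spermatocap

Analysis of spermatogenic capacity from single-cell RNA-seq atlases of the
human testis in idiopathic nonobstructive azoospermia (iNOA) — the condition
in which sperm production fails without an identified genetic or clinical
cause. Starting from a gene × cell count matrix with donor and group labels,
the pipeline:

1. **QC + normalization** — retain cells with > `min_genes` detected genes
   and > `min_transcripts` total counts; normalize to `log2(TPM/10 + 1)`
   with ribosomal/mitochondrial genes excluded first (TPM = tags per
   million, no gene-length term: 3′-UMI data).
2. **Donor stratification** — average-linkage `hclust` on 1 − Pearson
   correlation of donor pseudobulk profiles; the cluster containing the
   normal controls defines Class I, the remaining arrest classes are
   labelled by capacity ranking.
3. **Cell typing** — per-cell gene-set z-scores against marker panels for
   the 12 testis cell types (SSC → round spermatids + Sertoli/MIX/
   macrophages), argmax with a margin rule; composition χ² between groups.
4. **Cell-cycle activity** — z-scores of the canonical 43-gene G1/S and
   54-gene G2/M programs; a cell is "cycling" if its top phase score
   exceeds the 0.99 quantile of size-matched random-gene-set null scores;
   per-group active ratios with 2×2 χ² vs control.
5. **DEG frequency screen** — per-cell-type Wilcoxon tests vs NC
   (|Δ mean log2| ≥ 2, min.pct 0.25, Bonferroni); a gene scores frequency
   *k* if it is downregulated in **every** germ stage of *k* classes
   (stages absent under pachytene arrest are not required).
6. **Capacity score + trend modules** — spermatogenesis score = mean
   z-score of a capacity gene set per germ cell; groups ranked by median
   score; per-gene Spearman correlation of donor means vs severity rank
   (BH-adjusted), k-means trend modules with monotone end-modules as
   capacity predictors; overlap with external disease gene lists.
7. **Ligand–receptor networks** — CellPhoneDB-style statistic
   (mean ligand in sender + mean receptor in receiver)/2 with a strict 10%
   expression gate, label-permutation p-values, directed interaction-count
   networks and disease−control delta networks.

A seeded synthetic testis-atlas generator (`sim_config()` /
`generate_dataset()`) with planted ground truth — arrest classes,
composition shifts, downregulated genes, monotone trend genes, cycling
fractions, ligand–receptor boosts — makes every stage testable without
access to the controlled human data.

## Worked example

The numbered drivers under `analysis/` run the whole pipeline on the
default synthetic atlas (9 NC + 17 iNOA donors, 150 cells each, 2000
genes):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc_normalize.R
Rscript analysis/03_classes_types.R
Rscript analysis/04_cycle.R
Rscript analysis/05_deg_screen.R
Rscript analysis/06_capacity_trend.R
Rscript analysis/07_lr_network.R
```

Representative output (tables land in `results/`):

```
ARI vs planted donor classes: 1
Cell typing accuracy vs planted truth: 0.998 ( 5 unassigned )
Composition chi-square: statistic = 1117.2  df = 44  p = 2.48e-205

Cycling-cell ratio per group:
  ClassI  ClassII ClassIII  ClassIV       NC
   0.205    0.180    0.189    0.183    0.048

LELP1 frequency: 4
Genes down in SSC of all four classes: 10

ranking (best -> worst): NC > ClassI > ClassIII > ClassIV > ClassII

NC : 115 significant interactions; ST->SSC edge = 5
ClassII vs NC: net interaction change = -30 ; lost edges = 9
```

Reading it: donor clustering recovers the five planted donor groups
exactly (adjusted Rand index 1); disease germ cells cycle at ~4× the
control rate (the planted fractions are 0.20 vs 0.05); the planted
pan-class downregulated gene LELP1 reaches the maximal screen frequency
of 4; group capacity medians rank NC > Class I > Class III > Class IV >
Class II, the planted severity order; and pachytene-arrest classes lose
ligand–receptor interactions relative to control because the late germ
stages that received them are absent.

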