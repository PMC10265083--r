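---
title: "Methods: spermatogenic-capacity analysis of testicular single-cell atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spermatogenic-capacity analysis of testicular single-cell atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the data

`spermatocap` analyzes gene-by-cell count matrices from 3'-tag single-cell
RNA-seq of human testis, where each cell carries a donor label and each donor
belongs to a clinical group: normal controls (NC) or one of several classes
of idiopathic nonobstructive azoospermia (iNOA) with different spermatogenic
arrest points. Twelve cell types are modelled along the spermatogenic
trajectory — spermatogonial stem cells (SSC), differentiating and
differentiated spermatogonia, the meiotic stages leptotene (L), zygotene
(Z), pachytene (P), diplotene (D), a late spermatocyte state (SPC7), round
spermatids (RS) — plus three somatic populations: Sertoli cells (ST), a
peritubular-myoid/Leydig mixture (MIX), and testicular macrophages (tMphi).

The package is organised as an analysis pipeline (the numbered drivers under
`analysis/`) over library functions, so every stage is callable and testable
on its own.

# Normalization

Counts are converted to `log2(TPM/10 + 1)`. "TPM" here is **tag counts per
million per cell with no gene-length term**: in 3'-end UMI counting each
captured molecule yields one tag regardless of transcript length, so a
length denominator would be meaningless. Ribosomal (`^RP[SL]`) and
mitochondrial (`^MT-`) genes are removed **before** the per-cell rescaling;
the symbol rules are ours, since the underlying protocol description names
the exclusion but not the rule, and they are case-insensitive. The divisor
10 damps shot noise at typical 3'-tag depth; a zero count maps exactly to 0
and TPM 10 maps exactly to 1, which the tests pin down.

QC retains cells with strictly more than `min_genes` detected genes and
strictly more than `min_transcripts` total counts (defaults 2000 and 10000,
the thresholds appropriate for full-depth human testis libraries). The
strictness follows the wording "more than"; the boundary cases are tested
explicitly. On the bundled desk-scale simulations (2000-gene universe) the
drivers use proportionally scaled thresholds, since no cell can detect 2000
genes out of a 2000-gene universe; this is a property of the simulation
scale, not of the method.

# Gene-set z-scores

The scoring primitive for both cell-cycle activity and spermatogenic
capacity: each set gene is z-scored across the chosen cell subset using the
sample (n-1) standard deviation, and a cell's score is the mean z over set
genes. Genes with zero variance across the subset carry no information and
are dropped with a warning rather than scored as 0 — a zero would silently
shrink every cell's score toward 0 by a data-dependent amount. If all set
genes are constant the operation errors: the score is undefined, and
degenerate inputs should fail loudly.

Whether capacity z-scores should be computed over all spermatogenic cells
pooled or within groups is genuinely ambiguous in the source description; we
pool, because pooling keeps scores comparable across groups (a within-group
z-score would erase exactly the between-group differences the score is meant
to rank). The `cells` argument of `gene_set_zscore()` exposes the
alternative.

# Statistical tests

Two tests are shared across modules and implemented in the package:

* **Wilcoxon rank-sum** (`wilcoxon_test`): exact p by complete enumeration
  of the Mann-Whitney U distribution when `n1 + n2 <= 12` and the pooled
  sample is tie-free (at most 924 subsets, cheap and exactly verifiable);
  otherwise the normal approximation with tie correction and continuity
  correction. The switch point is where enumeration stops being free; the
  tests verify the exact branch against an independent enumeration oracle
  and the approximate branch against null calibration.
* **Pearson chi-square** (`chisq_test`): plain `sum((O-E)^2/E)` with
  `(r-1)(c-1)` degrees of freedom and **no Yates correction** — the
  composition tables compared here are r x c, not 2 x 2 designs where the
  correction has its rationale.

# Donor stratification

Donors are aggregated to pseudobulk (mean normalized expression over their
cells) and clustered by average-linkage hierarchical clustering on
1 - Pearson correlation over the top 2000 most variable genes. Correlation
distance is the standard transcriptome choice; the variable-gene cut keeps
the distance from being dominated by flat genes. The tree is cut at `k`
groups (default 5 over NC + patients jointly) and the group holding the
majority of control donors is labelled Class I — matching the clinical
definition of Class I as the patients whose expression co-clusters with
normals. Remaining groups get provisional labels in dendrogram order;
their clinical identity (II vs III vs IV) is established downstream by the
capacity ranking, not assumed from tree order. Donors are processed in
sorted-id order, which makes the result invariant to input order. Only the
expression part of the original expression-plus-histopathology
stratification is implemented: pathology images are not available to an
expression pipeline, and this divergence is deliberate.

# Cell typing

Every cell is scored against every cell-type marker panel with the gene-set
z-score and labelled by argmax, with cells whose top-two margin is below
`min_margin` (default 0.1 z-units) left "unassigned" instead of receiving a
coin-flip label. This cell-level scoring deliberately replaces the original
cluster-then-annotate procedure (PCA + jackstraw + UMAP + manual cluster
annotation): it removes the stochastic embedding while preserving the
testable contract — marker-consistent labels — and on the simulations it
recovers planted types with ~99.6-99.8% accuracy. The shipped panels
(`inst/extdata/marker_panels.tsv`) carry five classical markers per type
(e.g. UTF1/GFRA1/ID4/PIWIL4/LIN28A for SSC, WT1/SOX9/AMH for Sertoli,
PRM1/PRM2/TNP1 for round spermatids) and are user-replaceable; panel genes
were chosen to be disjoint from the cell-cycle program lists so the two
scoring systems cannot contaminate each other.

# Cell-cycle activity

G1/S and G2/M programs are scored per cell. The canonical 43-gene G1/S and
54-gene G2/M lists distributed with Seurat (`Seurat::cc.genes`) are used by
default — they match the 43/54 set sizes of the original analysis — and any
two-column TSV can be substituted. Because the original work never defines
"cells with active cell cycle", we adopt a self-calibrating rule: the null
distribution is built from `null_draws` random gene sets matched in size to
each phase set (scores pooled over draws and cells), and a cell is cycling
iff its larger phase score strictly exceeds the null's 0.99 quantile. The
strict inequality means an all-constant degenerate input yields zero active
cells. The rule's calibration (nominal false-call rate on structureless
data) and its recovery of planted cycling fractions are both tested.

# Differential expression and the frequency screen

Each disease class is compared with NC within each cell type. Genes reach
the Wilcoxon test only if expressed in at least 25% of cells on one side
(`min.pct = 0.25`) and the absolute mean difference on the log2 scale is at
least 2 — the interpretation of the legacy `thresh.use = 2` gate as an
absolute log-scale mean-difference threshold, exposed in configuration.
Bonferroni adjustment is applied within each (class, cell type) comparison,
matching the default of the wrapped legacy function; BH is available by
flag. Whether class qualification should use adjusted or nominal p was
unstated in the source; adjusted is used.

The frequency screen counts, per gene, the number of classes in which the
gene is differentially expressed (given direction) in **every** germ stage
of that class. Classes with pachytene arrest contribute only the stages
through P — D, SPC7 and RS do not exist there and must not block
qualification (the RS exclusion is explicit in the original figure legend).
A subset variant fixes the same stage list (e.g. just SSC) for every class.

# Capacity ranking and trend modules

The spermatogenesis score of a germ cell is the mean z-score over a capacity
gene set; groups are ranked by descending **median** (the distributions are
skewed, and only the order is interpreted), with all pairwise Wilcoxon tests
reported. Severity rank = position in the ranking.

Trend genes are found by Spearman correlation between **per-donor** germ-cell
mean expression and the donor's group severity rank — donor means, not
cells, are the unit, to avoid pseudoreplication from hundreds of correlated
cells per donor (a per-cell variant would inflate significance; the donor
version costs power but is honest at n = donors). Spearman makes the result
invariant to any strictly monotone relabelling of the ranks. BH adjustment
is used here (discovery framing), unlike the Bonferroni of the confirmatory
DEG screen. Genes are then clustered into `m = 5` modules by k-means
(25 restarts, seeded) on severity-ordered group-mean profiles standardized
per gene; modules are renumbered so Module 1 rises as capacity falls and
Module 5 falls. Five modules and k-means are configuration, chosen as the
simplest seedable method since the original names none. External-list
overlap is plain set arithmetic with no inference attached.

# Ligand-receptor networks

For a pair (ligand, receptor) and an ordered (sender, receiver) type pair,
the statistic is the mean of the ligand's average normalized expression in
sender cells and the receptor's average in receiver cells (zeros included).
Pairs pass only if ligand and receptor are each expressed (value > 0) in
strictly more than 10% of their respective type; an undetected gene means no
interaction, not an error. The null shuffles the type labels of **all**
cells jointly — preserving marginal type sizes — and reuses the same
permutation for every pair within an iteration;
`p = #(null >= observed)/n_perm`, so p-values live on the 1/n_perm grid and
p = 0 is possible (a +1-smoothed variant exists for FDR pipelines).
Significant interactions are counted into a directed type-by-type network;
node strength is the total incident significant count (the original's "
interaction strength" is not defined numerically, so we label ours
explicitly). Delta networks are elementwise disease-minus-reference with
per-edge gained/lost pair lists. Only simple one-to-one pairs are supported;
multi-subunit complexes are out of scope.

# The synthetic atlas generator

`sim_config()`/`generate_dataset()` produce a seeded gamma-Poisson atlas
whose defaults encode the study conditions: 9 NC donors plus 17 patients
(Class I 4, Class II 6, Class III 3, Class IV 4), 150 cells per donor, a
2000-gene universe, mean library size 20000 with NB dispersion 0.3 and a
lognormal (sd 0.1) donor depth factor. Composition per group mirrors the
qualitative statements of the source data: arrest at pachytene in Classes
II-IV (zero probability past P), excess L in Class II, excess Z in
Class III, depleted spermatogonia with excess L and Z in Class IV, and few
spermatids in Class I. Severity order is NC < I < III < IV < II.

Planted structure, all recorded in `sim_truth`:

* each type's five marker genes at 8x in its own cells;
* an 80-gene capacity program rising 0.35 log2 per germ stage and falling
  0.5 log2 per severity rank in germ cells — this is what the capacity
  score recovers;
* 18 downregulated genes (log2FC -3 in germ cells), ten of them — including
  LELP1 — in all four classes, five in three classes, three in one class,
  giving the frequency screen known answers;
* 50 monotone trend genes at +/-0.6 log2 per severity rank step;
* cycling fractions 0.20 in disease germ cells vs 0.05 in NC, implemented
  as a 4x boost of the G1/S and G2/M gene means in "cycling" cells;
* five Sertoli<->SSC ligand-receptor pairs at 8x, attenuated in the disease
  classes.

Where the source reports no number (per-stage composition proportions,
noise levels, effect sizes), values were fixed once at magnitudes a
practitioner would call realistic for deep 3'-tag data, and are not
revisited. The generator emulates overdispersed counts, composition shifts
and planted effects; it does **not** emulate doublets, ambient RNA, batch
effects, donor-specific composition noise beyond multinomial sampling, or
continuous developmental gradients within a stage. Passing tests therefore
demonstrate correctness of the statistical machinery under known truth, not
robustness to every artifact of real data.

# Problem sizes and numerical choices

The default atlas is 2000 genes x 3900 cells, generated in a few seconds,
which lets the test suite run replicate-level checks (20-seed ranking
recovery, 500-pair permutation calibration, 200-instance exact-test
enumeration) in minutes. Tolerances: TPM conservation is checked to 1e-6
relative; exact-test agreement to 1e-12; planted-recovery checks use the
binomial/rank statistics stated with each test rather than ad hoc margins.
Ties: donor clustering sorts donors by id before clustering (order
invariance); ranking ties keep a total order alphabetically and are
flagged; k-means ties are resolved by the seeded restarts. Degenerate
inputs (constant genes, empty groups, zero margins) error with messages
naming the offender wherever a silent default would bias a result.

# Known limitations

* The histopathology component of donor classification is not modelled.
* Marker panels cover five genes per type; real atlases warrant larger,
  tissue-calibrated panels via `marker_panel_set()`.
* The capacity gene set on real data should be the curated spermatogenesis
  GO list; the simulation substitutes its own planted program, and the
  drivers label it as such.
* Permutation p-values at n_perm = 1000 cannot resolve below 1e-3;
  raise `n_perm` for finer FDR control.
* The pipeline starts from counts; alignment, UMI collapsing and doublet
  handling are upstream concerns.
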