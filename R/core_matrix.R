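#' Construct a cell-level count matrix container
#'
#' The central data object of the pipeline: a gene x cell matrix of
#' nonnegative integer UMI/tag counts plus per-cell metadata (donor, group,
#' optionally cell_type) and per-gene ribosomal/mitochondrial flags.
#' Gene symbols are upper-cased and must be unique; flags are derived from the
#' symbols (`^RP[SL]` ribosomal, `^MT-` mitochondrial, case-insensitive).
#'
#' @param counts gene x cell matrix (dense or `Matrix` sparse) of nonnegative
#'   integer counts. Rownames are gene symbols, colnames cell ids, unless
#'   `gene_symbols` / `cell_ids` are given.
#' @param cell_meta data.frame with one row per cell carrying at least a
#'   `donor` column; a `group` column and a `cell_type` column are used by
#'   downstream stages when present.
#' @param gene_symbols,cell_ids optional overrides for dimnames.
#' @return An object of class `cell_matrix` with elements `counts`
#'   (a `dgCMatrix`), `gene_symbols`, `cell_ids`, `cell_meta`, `gene_flags`.
#' @export
cell_matrix <- function(counts, cell_meta = NULL, gene_symbols = NULL,
                        cell_ids = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) stop("counts contain negative values")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  gene_symbols <- toupper(if (is.null(gene_symbols)) rownames(counts) else gene_symbols)
  cell_ids <- if (is.null(cell_ids)) colnames(counts) else cell_ids
  if (is.null(gene_symbols) || length(gene_symbols) != nrow(counts))
    stop("gene_symbols missing or of wrong length")
  if (is.null(cell_ids) || length(cell_ids) != ncol(counts))
    stop("cell_ids missing or of wrong length")
  dup <- gene_symbols[duplicated(gene_symbols)]
  if (length(dup)) stop("duplicate gene symbols after upper-casing: ",
                        paste(utils::head(unique(dup), 5), collapse = ", "))
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  rownames(counts) <- gene_symbols
  colnames(counts) <- cell_ids
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = cell_ids)
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) != length(cell_ids))
      stop("cell_meta rows (", nrow(cell_meta), ") != number of cells (",
           length(cell_ids), ")")
    rownames(cell_meta) <- cell_ids
  }
  structure(list(
    counts = counts,
    gene_symbols = gene_symbols,
    cell_ids = cell_ids,
    cell_meta = cell_meta,
    gene_flags = data.frame(
      ribosomal = grepl("^RP[SL]", gene_symbols, ignore.case = TRUE),
      mitochondrial = grepl("^MT-", gene_symbols, ignore.case = TRUE),
      row.names = gene_symbols)
  ), class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("cell_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  cat("  ribosomal:", sum(x$gene_flags$ribosomal),
      " mitochondrial:", sum(x$gene_flags$mitochondrial), "\n")
  if (ncol(x$cell_meta))
    cat("  cell_meta:", paste(names(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Load a count matrix from disk
#'
#' Reads either a Matrix Market fixture directory (`matrix.mtx` +
#' `genes.tsv` + `cells.tsv`, as written by [write_fixture()]) or a dense TSV
#' with genes as rows and cells as columns. `cells.tsv` must carry a header
#' with at least `barcode`; `donor`, `group` and further columns are kept as
#' cell metadata.
#'
#' @param path directory (for `format = "mtx"`) or file (for `format = "tsv"`).
#' @param format `"mtx"` or `"tsv"`.
#' @return A [cell_matrix()].
#' @export
load_counts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    genes_f <- file.path(path, "genes.tsv")
    cells_f <- file.path(path, "cells.tsv")
    for (f in c(mtx, genes_f, cells_f))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- Matrix::readMM(mtx)
    genes <- utils::read.delim(genes_f, header = TRUE,
                               stringsAsFactors = FALSE)
    cells <- utils::read.delim(cells_f, header = TRUE,
                               stringsAsFactors = FALSE)
    if (nrow(genes) != nrow(m))
      stop("genes.tsv rows (", nrow(genes), ") != matrix rows (", nrow(m), ")")
    if (nrow(cells) != ncol(m))
      stop("cells.tsv rows (", nrow(cells), ") != matrix columns (", ncol(m), ")")
    meta <- cells[, setdiff(names(cells), "barcode"), drop = FALSE]
    cell_matrix(m, cell_meta = meta, gene_symbols = genes[[1]],
                cell_ids = cells$barcode)
  } else {
    if (!file.exists(path)) stop("missing file: ", path)
    tab <- utils::read.delim(path, header = TRUE, row.names = 1,
                             check.names = FALSE)
    cell_matrix(as.matrix(tab))
  }
}

#' Quality-control filter on detected genes and total transcripts
#'
#' Retains exactly the cells with *more than* `min_genes` detected genes
#' (counts > 0) and *more than* `min_transcripts` total counts; both
#' inequalities are strict. The defaults are the filtering thresholds used for
#' 3'-tag single-cell testis libraries (> 2000 genes, > 10000 transcripts).
#' The operation is idempotent.
#'
#' @param x a [cell_matrix()].
#' @param min_genes,min_transcripts nonnegative thresholds.
#' @return list with `matrix` (filtered `cell_matrix`) and `report`, a
#'   data.frame of removed cells with their statistics and removal reason.
#' @export
qc_filter <- function(x, min_genes = 2000, min_transcripts = 10000) {
  stopifnot(inherits(x, "cell_matrix"), min_genes >= 0, min_transcripts >= 0)
  n_genes <- Matrix::colSums(x$counts > 0)
  n_counts <- Matrix::colSums(x$counts)
  keep <- n_genes > min_genes & n_counts > min_transcripts
  reason <- character(sum(!keep))
  low_g <- n_genes[!keep] <= min_genes
  low_t <- n_counts[!keep] <= min_transcripts
  reason[low_g & !low_t] <- "low_genes"
  reason[!low_g & low_t] <- "low_transcripts"
  reason[low_g & low_t] <- "low_genes;low_transcripts"
  report <- data.frame(
    cell_id = x$cell_ids[!keep],
    n_genes = unname(n_genes[!keep]),
    n_transcripts = unname(n_counts[!keep]),
    reason = reason,
    stringsAsFactors = FALSE)
  out <- cell_matrix(x$counts[, keep, drop = FALSE],
                     cell_meta = x$cell_meta[keep, , drop = FALSE])
  list(matrix = out, report = report)
}

#' Normalize counts to log2(TPM/10 + 1)
#'
#' TPM here is tag counts per million per cell, with no gene-length term: the
#' assay is 3'-end UMI counting, where each transcript molecule yields one tag
#' regardless of length. Ribosomal and/or mitochondrial genes are removed
#' *before* the per-cell rescaling, so the remaining genes' TPM sums to 1e6 in
#' every cell.
#'
#' @param x a [cell_matrix()].
#' @param exclude character subset of `c("ribosomal", "mitochondrial")`;
#'   default excludes both.
#' @return An object of class `norm_matrix`: `values` (dense gene x cell
#'   matrix of log2(TPM/10+1)), `cell_meta`, `excluded_genes`.
#' @export
normalize_counts <- function(x, exclude = c("ribosomal", "mitochondrial")) {
  stopifnot(inherits(x, "cell_matrix"))
  if (length(exclude))
    exclude <- match.arg(exclude, c("ribosomal", "mitochondrial"),
                         several.ok = TRUE)
  drop <- rep(FALSE, nrow(x$counts))
  if ("ribosomal" %in% exclude) drop <- drop | x$gene_flags$ribosomal
  if ("mitochondrial" %in% exclude) drop <- drop | x$gene_flags$mitochondrial
  if (all(drop)) stop("no genes left after exclusion")
  if (ncol(x$counts) == 0) stop("no cells to normalize")
  counts <- x$counts[!drop, , drop = FALSE]
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("cells with zero total counts after exclusion: ",
         paste(utils::head(x$cell_ids[totals == 0], 5), collapse = ", "))
  tpm <- sweep(as.matrix(counts), 2, 1e6 / totals, "*")
  structure(list(
    values = log2(tpm / 10 + 1),
    cell_meta = x$cell_meta,
    excluded_genes = x$gene_symbols[drop]
  ), class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat("norm_matrix (log2(TPM/10+1)):", nrow(x$values), "genes x",
      ncol(x$values), "cells;", length(x$excluded_genes),
      "ribo/mito genes excluded\n")
  invisible(x)
}

#' Per-cell gene-set z-score
#'
#' For each set gene present in the matrix, expression is z-scored across the
#' chosen cell subset (sample standard deviation, n-1); a cell's score is the
#' mean z over the surviving set genes. Genes with zero variance across the
#' subset carry no ranking information and are dropped with a warning.
#' This is the scoring primitive behind both the cell-cycle phase scores and
#' the spermatogenesis capacity score.
#'
#' @param norm a `norm_matrix`.
#' @param set a [gene_set()] (or character vector of symbols).
#' @param cells optional character/logical/integer subset of cells; default all.
#' @return list with `score` (named numeric per cell), `n_genes_used`,
#'   `dropped` (zero-variance symbols).
#' @export
gene_set_zscore <- function(norm, set, cells = NULL) {
  stopifnot(inherits(norm, "norm_matrix"))
  genes <- if (inherits(set, "gene_set")) set$genes else toupper(set)
  set_name <- if (inherits(set, "gene_set")) set$name else "custom"
  v <- norm$values
  if (!is.null(cells)) v <- v[, cells, drop = FALSE]
  if (ncol(v) < 2) stop("need at least 2 cells to z-score")
  present <- intersect(genes, rownames(v))
  if (!length(present))
    stop("no genes of set '", set_name, "' present in the matrix")
  sub <- v[present, , drop = FALSE]
  mu <- rowMeans(sub)
  sd_ <- apply(sub, 1, stats::sd)
  usable <- sd_ > 0
  if (!any(usable))
    stop("all genes of set '", set_name, "' have zero variance")
  if (any(!usable))
    warning(sum(!usable), " zero-variance gene(s) dropped from set '",
            set_name, "': ",
            paste(utils::head(present[!usable], 5), collapse = ", "))
  z <- (sub[usable, , drop = FALSE] - mu[usable]) / sd_[usable]
  list(score = colMeans(z), n_genes_used = sum(usable),
       dropped = present[!usable])
}

#' Two-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' Exact p-value by complete enumeration of the U distribution when
#' `n1 + n2 <= 12` and the pooled sample has no ties; otherwise the normal
#' approximation with tie correction and continuity correction. The effect is
#' the difference of group means (group1 - group2) on the input scale.
#'
#' @param x,y numeric vectors (both nonempty).
#' @return list (`test_result`): `statistic` (Mann-Whitney U of `x`),
#'   `p_value`, `effect`, `n1`, `n2`, `method`.
#' @export
wilcoxon_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both groups must be nonempty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (n1 + n2 <= 12 && !ties) {
    # enumerate every assignment of n1 ranks out of n1+n2
    combos <- utils::combn(n1 + n2, n1)
    ranks_all <- seq_len(n1 + n2)
    u_all <- colSums(matrix(ranks_all[combos], nrow = n1)) -
      n1 * (n1 + 1) / 2
    p <- 2 * min(mean(u_all <= u), mean(u_all >= u))
    p <- min(1, p)
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(statistic = u, p_value = p,
                 effect = mean(x) - mean(y), n1 = n1, n2 = n2,
                 method = method), class = "test_result")
}

#' Pearson chi-square test on an r x c contingency table
#'
#' Plain Pearson statistic sum((O-E)^2/E) with df = (r-1)(c-1) and no
#' continuity correction: the composition tables compared here are r x c,
#' not 2 x 2 designs.
#'
#' @param tab matrix of nonnegative integer counts; all row and column sums
#'   must be positive.
#' @return `test_result` list: `statistic`, `p_value`, `df`, `n1` (rows),
#'   `n2` (columns).
#' @export
chisq_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("table contains negative entries")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0))
    stop("zero row margin at row ", which(rs == 0)[1])
  if (any(cs == 0))
    stop("zero column margin at column ", which(cs == 0)[1])
  e <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, p_value = p, df = df,
                 effect = NA_real_, n1 = nrow(tab), n2 = ncol(tab)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("statistic =", format(x$statistic, digits = 5),
      " p =", format(x$p_value, digits = 4))
  if (!is.null(x$effect) && !is.na(x$effect))
    cat("  effect =", format(x$effect, digits = 4))
  cat("\n")
  invisible(x)
}
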