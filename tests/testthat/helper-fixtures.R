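# Shared fixtures, generated in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

# default-condition synthetic atlas (26 donors, 2000 genes), one per run
sim_fixture <- function() {
  if (is.null(.fixture_cache$default)) {
    d <- generate_dataset(sim_config(seed = 7L))
    d$norm <- normalize_counts(d$matrix)
    .fixture_cache$default <- d
  }
  .fixture_cache$default
}

germ_mask <- function(d) d$truth$cells$true_type %in% germ_stage_order()

# wrap a plain matrix as a norm_matrix for unit tests
toy_norm <- function(values, meta = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("c%03d", seq_len(ncol(values)))
  if (is.null(meta)) meta <- data.frame(row.names = colnames(values))
  structure(list(values = values, cell_meta = meta,
                 excluded_genes = character()), class = "norm_matrix")
}

# subset a norm_matrix by cell index
norm_subset <- function(norm, idx) {
  norm$values <- norm$values[, idx, drop = FALSE]
  norm$cell_meta <- norm$cell_meta[idx, , drop = FALSE]
  norm
}

# small counts fixture with donors/groups for IO and QC tests
small_counts <- function(seed = 3L, n_genes = 60, n_cells = 30) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells)
  rownames(counts) <- c("MT-CO1", "RPS4", "RPL9",
                        sprintf("G%03d", seq_len(n_genes - 3)))
  colnames(counts) <- sprintf("c%03d", seq_len(n_cells))
  cell_matrix(counts, cell_meta = data.frame(
    donor = rep(c("d1", "d2", "d3"), length.out = n_cells),
    group = rep(c("NC", "ClassI"), length.out = n_cells)))
}
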