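#' Construct a gene set
#'
#' @param name set name.
#' @param genes character vector of symbols (upper-cased, de-duplicated).
#' @param role one of `g1s`, `g2m`, `spermatogenesis`, `apoptosis`,
#'   `marker_panel`, `custom`.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes, role = "custom") {
  role <- match.arg(role, c("g1s", "g2m", "spermatogenesis", "apoptosis",
                            "marker_panel", "custom"))
  genes <- unique(toupper(genes))
  if (!length(genes)) stop("gene set '", name, "' is empty")
  structure(list(name = name, role = role, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "' (", x$role, "): ", length(x$genes),
      " genes\n", sep = "")
  invisible(x)
}

#' Load gene sets from a two-column TSV
#'
#' Expects a header line and columns `set_name`, `gene_symbol` (extra columns
#' ignored). Returns one [gene_set()] per distinct set name.
#'
#' @param path TSV file.
#' @param role role tag applied to every set read.
#' @return named list of `gene_set` objects.
#' @export
load_gene_sets <- function(path, role = "custom") {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("set_name", "gene_symbol") %in% names(tab)))
    stop("gene-set TSV needs columns set_name, gene_symbol: ", path)
  sets <- split(tab$gene_symbol, tab$set_name)
  lapply(stats::setNames(names(sets), names(sets)),
         function(nm) gene_set(nm, sets[[nm]], role = role))
}

#' Canonical G1/S and G2/M cell-cycle gene sets
#'
#' Returns the widely used 43-gene G1/S (S-phase) and 54-gene G2/M programs
#' distributed with Seurat (`Seurat::cc.genes`), wrapped as [gene_set()]
#' objects. Any replacement list can be supplied to the scoring functions via
#' [load_gene_sets()] instead.
#'
#' @return list with elements `g1s` and `g2m`.
#' @export
cycle_gene_sets <- function() {
  if (!requireNamespace("Seurat", quietly = TRUE))
    stop("cycle_gene_sets() needs the Seurat package for its canonical ",
         "cell-cycle gene lists; supply your own via load_gene_sets()")
  cc <- Seurat::cc.genes
  list(g1s = gene_set("G1S", cc$s.genes, role = "g1s"),
       g2m = gene_set("G2M", cc$g2m.genes, role = "g2m"))
}

#' Default marker panels for the twelve testis cell types
#'
#' Small, user-replaceable panels of classical markers for the nine germ
#' stages (SSC through round spermatids) and the three somatic populations
#' (Sertoli, peritubular-myoid/Leydig mixture, testicular macrophages), read
#' from the TSV shipped in `inst/extdata/marker_panels.tsv`.
#'
#' @return a `marker_panel_set`: list with `panels` (named list of
#'   `gene_set`) and `stage_order` / `somatic_labels`.
#' @export
default_marker_panels <- function() {
  path <- system.file("extdata", "marker_panels.tsv",
                      package = "spermatocap", mustWork = TRUE)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  panels <- lapply(split(tab, tab$cell_type), function(d)
    gene_set(d$cell_type[1], d$gene, role = "marker_panel"))
  marker_panel_set(panels)
}

#' Assemble a marker panel set
#'
#' @param panels named list of `gene_set` objects, one per cell-type label.
#' @param stage_order germ-stage labels in developmental order.
#' @param somatic_labels somatic cell-type labels.
#' @export
marker_panel_set <- function(panels,
                             stage_order = germ_stage_order(),
                             somatic_labels = somatic_labels_default()) {
  stopifnot(length(panels) > 0, !is.null(names(panels)))
  if (anyDuplicated(stage_order)) stop("duplicate stage labels")
  missing <- setdiff(c(stage_order, somatic_labels), names(panels))
  if (length(missing))
    stop("no marker panel for: ", paste(missing, collapse = ", "))
  structure(list(panels = panels[c(stage_order, somatic_labels)],
                 stage_order = stage_order,
                 somatic_labels = somatic_labels),
            class = "marker_panel_set")
}

#' Germ-cell stage labels in developmental order
#'
#' SSC, differentiating and differentiated spermatogonia, then the meiotic
#' stages leptotene (L), zygotene (Z), pachytene (P), diplotene (D), a late
#' spermatocyte state (SPC7), and round spermatids (RS).
#' @export
germ_stage_order <- function() {
  c("SSC", "Diff.ing SPG", "Diff.ed SPG", "L", "Z", "P", "D", "SPC7", "RS")
}

#' Somatic testis cell-type labels
#'
#' Sertoli cells (ST), the peritubular-myoid plus Leydig mixture (MIX), and
#' testicular macrophages (tMphi).
#' @export
somatic_labels_default <- function() c("ST", "MIX", "tMphi")

#' Default ligand-receptor pair table
#'
#' A small simple-pair database (pair_id, ligand, receptor) shipped as TSV,
#' seeded with pairs relevant to Sertoli-spermatogonial signalling
#' (RSPO3-LGR4, NECTIN2-CD226, JAG2-NOTCH1, CSF1-SIRPA, CXCL12-CXCR4, ...).
#' Replace with any TSV of the same three columns via [load_lr_pairs()].
#' @return data.frame with columns pair_id, ligand, receptor.
#' @export
default_lr_pairs <- function() {
  load_lr_pairs(system.file("extdata", "lr_pairs.tsv",
                            package = "spermatocap", mustWork = TRUE))
}

#' Load a ligand-receptor pair table from TSV
#' @param path TSV with header pair_id, ligand, receptor.
#' @export
load_lr_pairs <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("pair_id", "ligand", "receptor")
  if (!all(need %in% names(tab)))
    stop("LR pair TSV needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$pair_id)) stop("duplicate pair_id in ", path)
  if (any(!nzchar(tab$ligand)) || any(!nzchar(tab$receptor)))
    stop("empty ligand or receptor symbol in ", path)
  tab$ligand <- toupper(tab$ligand)
  tab$receptor <- toupper(tab$receptor)
  tab[need]
}
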