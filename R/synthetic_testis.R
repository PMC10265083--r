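#' Configuration for the synthetic testis atlas generator
#'
#' Builds a seeded gamma-Poisson (negative binomial) simulation of a
#' multi-donor testis single-cell atlas with known ground truth. The default
#' configuration mirrors the structure of the iNOA study population: 9 normal
#' control (NC) donors plus 17 idiopathic-azoospermia donors split into four
#' arrest classes (Class I 4, Class II 6, Class III 3, Class IV 4); twelve
#' cell types ordered along spermatogenesis; meiotic arrest at pachytene in
#' Classes II-IV (no D/SPC7/RS cells); class-specific composition shifts
#' (Class II more leptotene, Class III more zygotene, Class IV fewer
#' spermatogonia with more L and Z); a capacity program of genes whose germ
#' cell expression declines with disease severity; planted downregulated
#' genes, monotone trend genes, elevated cycling-cell fractions in disease,
#' and ligand-receptor pairs between Sertoli cells and spermatogonial stem
#' cells. Severity order is NC < ClassI < ClassIII < ClassIV < ClassII.
#'
#' @param n_donors_per_group named integer vector, donors per group.
#' @param cells_per_donor cells sampled per donor.
#' @param n_genes size of the gene universe (filler genes pad the planted
#'   symbols up to this size).
#' @param groups ordered group labels.
#' @param stage_order germ stages in developmental order.
#' @param somatic_labels somatic cell types.
#' @param arrest_stage named map group -> last germ stage present.
#' @param composition group x cell-type proportion matrix (rows sum to 1).
#' @param severity_rank named map group -> severity rank (1 = best capacity).
#' @param library_size_mean expected total counts per cell.
#' @param dispersion negative-binomial overdispersion (size = 1/dispersion).
#' @param marker_fold expression fold for a cell type's own marker genes.
#' @param program_stage_log2fc log2 increase of capacity-program genes per
#'   germ stage step.
#' @param program_severity_log2fc log2 change of capacity-program genes per
#'   severity rank step in germ cells (negative: capacity declines).
#' @param planted_down_genes data.frame(group, gene, log2fc) of germ-cell
#'   downregulation planted per group.
#' @param planted_trend_genes data.frame(gene, slope) with slope the log2
#'   change per severity rank step in germ cells.
#' @param planted_cycling_fraction named map group -> fraction of germ cells
#'   given the cell-cycle program boost.
#' @param cycle_boost fold applied to G1/S and G2/M genes in cycling cells.
#' @param cycle_genes character vector of cycle gene symbols to plant
#'   (default: the canonical 43 + 54 gene lists from [cycle_gene_sets()]).
#' @param planted_lr_pairs data.frame(pair_id, ligand, receptor, sender_type,
#'   receiver_type, strength): ligand boosted in sender cells, receptor in
#'   receiver cells.
#' @param lr_group_atten named map group -> attenuation of the planted LR
#'   boost (1 keeps the full boost; < 1 weakens signalling in that group).
#' @param donor_sd standard deviation of the per-donor log library-size factor.
#' @param seed integer seed governing all draws.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(
    n_donors_per_group = c(NC = 9, ClassI = 4, ClassII = 6,
                           ClassIII = 3, ClassIV = 4),
    cells_per_donor = 150,
    n_genes = 2000,
    groups = c("NC", "ClassI", "ClassII", "ClassIII", "ClassIV"),
    stage_order = germ_stage_order(),
    somatic_labels = somatic_labels_default(),
    arrest_stage = c(NC = "RS", ClassI = "RS", ClassII = "P",
                     ClassIII = "P", ClassIV = "P"),
    composition = default_composition(),
    severity_rank = c(NC = 1, ClassI = 2, ClassIII = 3,
                      ClassIV = 4, ClassII = 5),
    library_size_mean = 20000,
    dispersion = 0.3,
    marker_fold = 8,
    program_stage_log2fc = 0.35,
    program_severity_log2fc = -0.5,
    planted_down_genes = default_down_genes(),
    planted_trend_genes = default_trend_genes(),
    planted_cycling_fraction = c(NC = 0.05, ClassI = 0.20, ClassII = 0.20,
                                 ClassIII = 0.20, ClassIV = 0.20),
    cycle_boost = 4,
    cycle_genes = NULL,
    planted_lr_pairs = default_planted_lr(),
    lr_group_atten = c(NC = 1, ClassI = 1, ClassII = 0.2,
                       ClassIII = 0.35, ClassIV = 0.2),
    donor_sd = 0.1,
    seed = 1L) {
  if (is.null(cycle_genes))
    cycle_genes <- unlist(lapply(cycle_gene_sets(), `[[`, "genes"),
                          use.names = FALSE)
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Default group x cell-type composition matrix
#'
#' Proportions emulate the study's qualitative composition statements:
#' controls are rich in late stages (round spermatids); Class I retains all
#' types with fewer spermatids; Classes II-IV stop at pachytene, with excess
#' leptotene in Class II, excess zygotene in Class III, and depleted
#' spermatogonia plus excess L and Z in Class IV.
#' @export
default_composition <- function() {
  types <- c(germ_stage_order(), somatic_labels_default())
  m <- rbind(
    NC       = c(.06, .05, .05, .06, .07, .14, .08, .07, .22, .12, .05, .03),
    ClassI   = c(.07, .06, .06, .08, .09, .16, .07, .05, .08, .15, .08, .05),
    ClassII  = c(.08, .07, .07, .24, .12, .14, 0, 0, 0, .16, .08, .04),
    ClassIII = c(.08, .07, .07, .10, .26, .14, 0, 0, 0, .16, .08, .04),
    ClassIV  = c(.03, .03, .03, .20, .20, .15, 0, 0, 0, .22, .09, .05))
  colnames(m) <- types
  m
}

#' Default planted downregulated genes
#'
#' LELP1 plus nine synthetic genes down (log2FC -3) in germ cells of all four
#' disease classes (frequency 4 in the screen); five genes down in three
#' classes; three genes down in Class IV only.
#' @export
default_down_genes <- function() {
  freq4 <- c("LELP1", sprintf("DOWN%02d", 2:10))
  freq3 <- sprintf("DOWN%02d", 11:15)
  freq1 <- sprintf("DOWN%02d", 16:18)
  rbind(
    expand.grid(group = c("ClassI", "ClassII", "ClassIII", "ClassIV"),
                gene = freq4, log2fc = -3, stringsAsFactors = FALSE),
    expand.grid(group = c("ClassI", "ClassIII", "ClassIV"),
                gene = freq3, log2fc = -3, stringsAsFactors = FALSE),
    expand.grid(group = "ClassIV",
                gene = freq1, log2fc = -3, stringsAsFactors = FALSE))
}

#' Default planted monotone trend genes
#'
#' 25 genes rising and 25 genes falling with severity rank, at +/-0.6 log2
#' per rank step (range 2.4 log2 across the five ranks).
#' @export
default_trend_genes <- function() {
  data.frame(
    gene = c(sprintf("TRUP%02d", 1:25), sprintf("TRDN%02d", 1:25)),
    slope = rep(c(0.6, -0.6), each = 25),
    stringsAsFactors = FALSE)
}

#' Default planted ligand-receptor pairs
#'
#' Sertoli-to-SSC and SSC-to-Sertoli signalling at 8x strength, attenuated
#' per group by `lr_group_atten`.
#' @export
default_planted_lr <- function() {
  data.frame(
    pair_id = c("RSPO3_LGR4", "NECTIN2_CD226", "JAG2_NOTCH1",
                "CSF1_SIRPA", "CXCL12_CXCR4"),
    ligand = c("RSPO3", "NECTIN2", "JAG2", "CSF1", "CXCL12"),
    receptor = c("LGR4", "CD226", "NOTCH1", "SIRPA", "CXCR4"),
    sender_type = c("ST", "ST", "ST", "ST", "ST"),
    receiver_type = c("SSC", "SSC", "SSC", "tMphi", "SSC"),
    strength = 8,
    stringsAsFactors = FALSE)
}

#' Capacity-program gene symbols of a configuration
#' @param n_program number of program genes.
#' @keywords internal
program_gene_symbols <- function(n_program = 80) sprintf("SPRM%03d", seq_len(n_program))

validate_sim_config <- function(cfg) {
  types <- c(cfg$stage_order, cfg$somatic_labels)
  if (!setequal(names(cfg$n_donors_per_group), cfg$groups))
    stop("configuration error in n_donors_per_group: groups mismatch")
  if (!all(cfg$groups %in% rownames(cfg$composition)))
    stop("configuration error in composition: missing group rows")
  if (!setequal(colnames(cfg$composition), types))
    stop("configuration error in composition: unknown cell type column(s): ",
         paste(setdiff(colnames(cfg$composition), types), collapse = ", "))
  rs <- rowSums(cfg$composition[cfg$groups, , drop = FALSE])
  bad <- abs(rs - 1) > 1e-9
  if (any(bad))
    stop("configuration error in composition: proportions for group ",
         names(rs)[bad][1], " sum to ", rs[bad][1], ", not 1")
  for (g in cfg$groups) {
    a <- cfg$arrest_stage[[g]]
    if (!a %in% cfg$stage_order)
      stop("configuration error in arrest_stage: unknown stage '", a,
           "' for group ", g)
    late <- cfg$stage_order[seq_along(cfg$stage_order) >
                              match(a, cfg$stage_order)]
    if (length(late) && any(cfg$composition[g, late] > 0))
      stop("configuration error in composition: group ", g,
           " has nonzero proportion past its arrest stage ", a)
  }
  if (!setequal(names(cfg$severity_rank), cfg$groups))
    stop("configuration error in severity_rank: groups mismatch")
  universe <- sim_gene_universe(cfg)
  planted <- unique(c(cfg$planted_down_genes$gene,
                      cfg$planted_trend_genes$gene,
                      cfg$planted_lr_pairs$ligand,
                      cfg$planted_lr_pairs$receptor))
  absent <- setdiff(toupper(planted), universe)
  if (length(absent))
    stop("configuration error: planted gene(s) not in the gene universe: ",
         paste(utils::head(absent, 5), collapse = ", "))
  invisible(cfg)
}

#' Gene universe implied by a configuration
#'
#' Marker panel genes, cycle genes, capacity-program genes, planted down and
#' trend genes, planted LR genes, a handful of ribosomal/mitochondrial
#' symbols, then filler genes up to `n_genes`.
#' @param cfg a `sim_config`.
#' @export
sim_gene_universe <- function(cfg) {
  panels <- default_marker_panels()
  specials <- unique(toupper(c(
    unlist(lapply(panels$panels, `[[`, "genes"), use.names = FALSE),
    cfg$cycle_genes,
    program_gene_symbols(),
    cfg$planted_down_genes$gene,
    cfg$planted_trend_genes$gene,
    cfg$planted_lr_pairs$ligand, cfg$planted_lr_pairs$receptor,
    paste0("RPS", 1:8), paste0("RPL", 1:8),
    paste0("MT-", c("CO1", "CO2", "CO3", "ND1", "ND2", "CYB")))))
  if (cfg$n_genes < length(specials) + 50)
    stop("configuration error in n_genes: need at least ",
         length(specials) + 50, " genes")
  c(specials, sprintf("GENE%04d", seq_len(cfg$n_genes - length(specials))))
}

#' Generate a synthetic testis atlas with ground truth
#'
#' Draws per-donor cell-type counts from the configured composition, then
#' per-cell counts as gamma-Poisson with a gene mean program assembled from:
#' a lognormal baseline; an 8x boost of each type's marker genes; a capacity
#' program rising along germ stages and attenuated with severity in germ
#' cells; planted germ-cell downregulation, monotone trend genes, cycling
#' boosts, and ligand-receptor boosts. The same seed yields identical output.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (a [cell_matrix()] with donor/group metadata)
#'   and `truth` (class `sim_truth`): per-cell `cells` data.frame (cell_id,
#'   donor, group, true_type, cycling), planted tables, gene-role lists,
#'   severity ranks and the config.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  universe <- sim_gene_universe(cfg)
  ng <- length(universe)
  panels <- default_marker_panels()
  types <- c(cfg$stage_order, cfg$somatic_labels)
  germ <- cfg$stage_order
  program <- program_gene_symbols()
  idx <- function(genes) match(intersect(toupper(genes), universe), universe)

  # baseline expression weights; planted genes kept well-expressed so the
  # screens see them, ribo/mito abundant as in real cells
  base <- stats::rlnorm(ng, meanlog = 0, sdlog = 1.2)
  med <- stats::median(base)
  base[idx(c(cfg$planted_down_genes$gene, cfg$planted_trend_genes$gene,
             program, cfg$cycle_genes,
             cfg$planted_lr_pairs$ligand, cfg$planted_lr_pairs$receptor))] <- 4 * med
  base[grepl("^RP[SL]|^MT-", universe)] <- 12 * med

  prog_i <- idx(program)
  stage_fac <- 2^(cfg$program_stage_log2fc * (seq_along(germ) - 1))
  names(stage_fac) <- germ
  marker_i <- lapply(panels$panels, function(p) idx(p$genes))
  cyc_i <- idx(cfg$cycle_genes)
  trend_i <- idx(cfg$planted_trend_genes$gene)
  trend_slope <- cfg$planted_trend_genes$slope

  donors <- unlist(lapply(cfg$groups, function(g)
    paste0(g, "_d", seq_len(cfg$n_donors_per_group[[g]]))), use.names = FALSE)
  donor_group <- rep(cfg$groups, cfg$n_donors_per_group[cfg$groups])
  names(donor_group) <- donors
  donor_fac <- exp(stats::rnorm(length(donors), 0, cfg$donor_sd))
  names(donor_fac) <- donors

  blocks <- list(); meta <- list(); bi <- 0L
  for (d in donors) {
    g <- donor_group[[d]]
    sev <- cfg$severity_rank[[g]]
    n_type <- stats::rmultinom(1, cfg$cells_per_donor,
                               cfg$composition[g, types])[, 1]
    down_d <- cfg$planted_down_genes[cfg$planted_down_genes$group == g, ]
    for (ty in types[n_type > 0]) {
      n <- n_type[[ty]]
      is_germ <- ty %in% germ
      cyc <- if (is_germ)
        stats::rbinom(n, 1, cfg$planted_cycling_fraction[[g]]) == 1
      else rep(FALSE, n)
      w <- base
      w[marker_i[[ty]]] <- w[marker_i[[ty]]] * cfg$marker_fold
      if (is_germ) {
        w[prog_i] <- w[prog_i] * stage_fac[[ty]] *
          2^(cfg$program_severity_log2fc * (sev - 1))
        w[trend_i] <- w[trend_i] * 2^(trend_slope * (sev - 1))
        if (nrow(down_d))
          w[idx(down_d$gene)] <- w[idx(down_d$gene)] * 2^down_d$log2fc
      }
      lr <- cfg$planted_lr_pairs
      att <- cfg$lr_group_atten[[g]]
      for (k in seq_len(nrow(lr))) {
        f <- 1 + (lr$strength[k] - 1) * att
        if (lr$sender_type[k] == ty)
          w[idx(lr$ligand[k])] <- w[idx(lr$ligand[k])] * f
        if (lr$receiver_type[k] == ty)
          w[idx(lr$receptor[k])] <- w[idx(lr$receptor[k])] * f
      }
      for (cyc_state in unique(cyc)) {
        nn <- sum(cyc == cyc_state)
        ww <- w
        if (cyc_state) ww[cyc_i] <- ww[cyc_i] * cfg$cycle_boost
        mu <- ww / sum(ww) * cfg$library_size_mean * donor_fac[[d]]
        cnt <- matrix(stats::rnbinom(ng * nn, mu = rep(mu, nn),
                                     size = 1 / cfg$dispersion),
                      nrow = ng)
        bi <- bi + 1L
        blocks[[bi]] <- cnt
        meta[[bi]] <- data.frame(donor = d, group = g, true_type = ty,
                                 cycling = cyc_state,
                                 stringsAsFactors = FALSE)[rep(1, nn), ]
      }
    }
  }
  counts <- do.call(cbind, blocks)
  cells <- do.call(rbind, meta)
  cells$cell_id <- sprintf("CELL%05d", seq_len(nrow(cells)))
  rownames(cells) <- cells$cell_id
  rownames(counts) <- universe
  colnames(counts) <- cells$cell_id

  mat <- cell_matrix(counts,
                     cell_meta = cells[, c("donor", "group")])
  truth <- structure(list(
    cells = cells[, c("cell_id", "donor", "group", "true_type", "cycling")],
    planted_down_genes = cfg$planted_down_genes,
    planted_trend_genes = cfg$planted_trend_genes,
    planted_lr_pairs = cfg$planted_lr_pairs,
    program_genes = program,
    cycle_genes = toupper(cfg$cycle_genes),
    severity_rank = cfg$severity_rank,
    config = cfg
  ), class = "sim_truth")
  list(matrix = mat, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$cells), "cells,",
      length(unique(x$cells$donor)), "donors,",
      length(unique(x$cells$group)), "groups\n")
  invisible(x)
}

#' Hash of a simulation configuration
#'
#' MD5 of the ASCII-serialized configuration; changes whenever any field
#' changes. Recorded in fixture manifests for provenance.
#' @param cfg a `sim_config`.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(unclass(cfg), tmp, ascii = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write a synthetic dataset to a fixture directory
#'
#' Emits `matrix.mtx` (Matrix Market), `genes.tsv`, `cells.tsv` (barcode,
#' donor, group), `truth.tsv` and `manifest.yaml` (seed, config hash,
#' dimensions). Round-trips losslessly through [load_counts()].
#'
#' @param mat a [cell_matrix()].
#' @param truth the matching `sim_truth`.
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_fixture <- function(mat, truth, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  Matrix::writeMM(mat$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(symbol = mat$gene_symbols),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cells <- data.frame(barcode = mat$cell_ids, mat$cell_meta,
                      check.names = FALSE)
  utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$cells, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(seed = truth$config$seed,
                   config_hash = config_hash(truth$config),
                   n_genes = nrow(mat$counts), n_cells = ncol(mat$counts))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
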