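#' Simulate a stage-structured count matrix with planted specific features
#'
#' Expression-level companion of the read-level simulator: per-feature
#' baseline expectations are drawn once (log-normal around `base_mean`),
#' planted features get a `fold`-times expectation in one stage, and counts
#' are Poisson. Useful for studying the operating characteristics of
#' stage-specific selection without sequence-level simulation.
#'
#' @param n_features total number of features
#' @param n_planted number of planted stage-specific features
#' @param stages ordered stage labels
#' @param cells_per_stage cells per stage
#' @param base_mean mean baseline expected count per cell
#' @param fold peak-stage fold change of planted features
#' @param seed integer seed
#' @return list with `sce` (counts + cpm10, colData stage) and `truth`
#'   (feature_id, planted, peak_stage)
#' @export
simulate_stage_counts <- function(n_features = 2000L, n_planted = 200L,
                                  stages = paste0("S", 1:8),
                                  cells_per_stage = 20L, base_mean = 10,
                                  fold = 8, seed = 1L) {
  set.seed(as.integer(seed %% 2147483647))
  feats <- sprintf("F%05d", seq_len(n_features))
  base <- stats::rlnorm(n_features, log(base_mean), 0.4)
  lambda <- matrix(rep(base, length(stages)), ncol = length(stages),
                   dimnames = list(feats, stages))
  planted <- sample(feats, n_planted)
  peak <- sample(stages, n_planted, replace = TRUE)
  for (i in seq_len(n_planted)) lambda[planted[i], peak[i]] <-
    lambda[planted[i], peak[i]] * fold
  cells <- sprintf("c%04d", seq_len(length(stages) * cells_per_stage))
  st <- rep(stages, each = cells_per_stage)
  lam <- lambda[, st, drop = FALSE]
  counts <- matrix(rpois(length(lam), lam), nrow = n_features,
                   dimnames = list(feats, cells))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(stage = st, row.names = cells))
  sce <- normalize_cpm10(sce)
  truth <- data.frame(feature_id = feats, planted = feats %in% planted,
                      peak_stage = NA_character_)
  truth$peak_stage[match(planted, feats)] <- peak
  list(sce = sce, truth = truth)
}

#' Simulate pooled isoform counts with planted switches
#'
#' Each gene has two isoforms; the major-isoform fraction is constant
#' across the stage boundary for null genes and flips `hi -> 1 - hi` for
#' planted switch genes. Gene totals are Poisson around `umis_per_stage`
#' split multinomially over cells.
#'
#' @param n_genes number of genes
#' @param n_switch number of planted switch genes
#' @param stages two stage labels
#' @param cells_per_stage cells per stage
#' @param umis_per_stage expected gene UMIs pooled per stage
#' @param hi major-isoform fraction on the high side (default 0.9)
#' @param seed integer seed
#' @return list with `sce` (isoform counts), `gene_map`, `truth`
#'   (gene_id, switched)
#' @export
simulate_switch_counts <- function(n_genes = 1000L, n_switch = 0L,
                                   stages = c("A", "B"),
                                   cells_per_stage = 10L,
                                   umis_per_stage = 200, hi = 0.9,
                                   seed = 1L) {
  set.seed(as.integer(seed %% 2147483647))
  genes <- sprintf("G%05d", seq_len(n_genes))
  sw <- c(rep(TRUE, n_switch), rep(FALSE, n_genes - n_switch))
  frac_null <- runif(n_genes, 0.2, 0.8)
  f1 <- ifelse(sw, hi, frac_null)
  f2 <- ifelse(sw, 1 - hi, frac_null)
  cells <- sprintf("c%04d", seq_len(2L * cells_per_stage))
  st <- rep(stages, each = cells_per_stage)
  iso_ids <- c(paste0(genes, ".1"), paste0(genes, ".2"))
  counts <- matrix(0L, nrow = 2L * n_genes, ncol = length(cells),
                   dimnames = list(iso_ids, cells))
  for (s in 1:2) {
    cols <- which(st == stages[s])
    tot <- rpois(n_genes, umis_per_stage)
    a <- rbinom(n_genes, tot, if (s == 1L) f1 else f2)
    b <- tot - a
    for (g in seq_len(n_genes)) {
      if (tot[g] == 0L) next
      counts[g, cols] <- counts[g, cols] +
        as.integer(stats::rmultinom(1L, a[g], rep(1, length(cols))))
      counts[n_genes + g, cols] <- counts[n_genes + g, cols] +
        as.integer(stats::rmultinom(1L, b[g], rep(1, length(cols))))
    }
  }
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(stage = st, row.names = cells))
  gene_map <- data.frame(feature_id = iso_ids,
                         gene_id = rep(genes, 2L))
  list(sce = sce, gene_map = gene_map,
       truth = data.frame(gene_id = genes, switched = sw))
}

#' Simulate coupled TE-locus / gene expression
#'
#' Builds a toy reference, pairs each gene-adjacent TE locus (within
#' `adjacent_max`) with its nearest gene, and draws counts where each
#' coupled pair shares a per-cell log-normal activity factor (plus
#' independent Poisson noise), while gene-distal loci and all other genes
#' use independent factors. This emulates TE loci acting as local
#' regulatory elements whose activity tracks their neighbour gene.
#'
#' @param seed integer seed
#' @param n_genes,n_te_loci reference sizing
#' @param n_cells number of cells
#' @param te_mean,gene_mean expected counts per cell
#' @param coupling sd of the shared log-activity factor
#' @param adjacent_max adjacency threshold (nt)
#' @return list with `te_sce`, `gene_sce`, `reference`, `pairs`
#'   (te_locus_id, gene_id, coupled)
#' @export
simulate_coupled_te_gene <- function(seed = 1L, n_genes = 12L,
                                     n_te_loci = 30L, n_cells = 100L,
                                     te_mean = 8, gene_mean = 20,
                                     coupling = 0.8,
                                     adjacent_max = 10000L) {
  # wide intergenic gaps: each gene-adjacent TE locus has exactly one gene
  # within the adjacency distance, so adjacency coincides with coupling
  ref <- build_toy_reference(seed, n_chromosomes = 2L, n_genes = n_genes,
                             n_te_loci = n_te_loci, te_near_frac = 0.5,
                             chrom_length = 300000L,
                             gap_range = c(19000L, 23000L))
  set.seed(as.integer(child_seed(seed, 31L)))
  te <- ref$te_loci; genes <- ref$genes
  # nearest gene within threshold, per locus
  partner <- rep(NA_character_, nrow(te))
  for (i in seq_len(nrow(te))) {
    same <- which(genes$chrom == te$chrom[i])
    if (length(same) == 0L) next
    d <- interval_gap(te$start[i], te$end[i], genes$start[same],
                      genes$end[same])
    j <- same[which.min(d)]
    if (min(d) < adjacent_max) partner[i] <- genes$gene_id[j]
  }
  cells <- sprintf("c%03d", seq_len(n_cells))
  gene_factor <- matrix(stats::rlnorm(nrow(genes) * n_cells, 0, coupling),
                        nrow = nrow(genes),
                        dimnames = list(genes$gene_id, cells))
  te_counts <- matrix(0L, nrow(te), n_cells,
                      dimnames = list(te$locus_id, cells))
  for (i in seq_len(nrow(te))) {
    f <- if (!is.na(partner[i])) gene_factor[partner[i], ]
         else stats::rlnorm(n_cells, 0, coupling)
    te_counts[i, ] <- rpois(n_cells, te_mean * f)
  }
  gene_counts <- matrix(
    rpois(length(gene_factor), gene_mean * gene_factor),
    nrow = nrow(genes), dimnames = dimnames(gene_factor))
  as_sce <- function(m) {
    s <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = methods::as(m, "CsparseMatrix")),
      colData = S4Vectors::DataFrame(stage = rep("S1", n_cells),
                                     row.names = cells))
    normalize_cpm10(s)
  }
  list(te_sce = as_sce(te_counts), gene_sce = as_sce(gene_counts),
       reference = ref,
       pairs = data.frame(te_locus_id = te$locus_id, gene_id = partner,
                          coupled = !is.na(partner)))
}
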