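#' Stage design: ordered stages and cell labels
#'
#' @param stage_per_cell named character vector (cell/barcode -> stage)
#' @param stages ordered stage labels (default: order of first appearance)
#' @return a `stage_design` list with `stages`, `cell_stage`, and
#'   `adjacent_pairs` (2-column matrix of consecutive stages)
#' @export
stage_design <- function(stage_per_cell, stages = NULL) {
  stages <- stages %||% unique(unname(stage_per_cell))
  stopifnot(length(stages) >= 2L, all(stage_per_cell %in% stages),
            !is.null(names(stage_per_cell)))
  pairs <- cbind(stages[-length(stages)], stages[-1L])
  structure(list(stages = stages, cell_stage = stage_per_cell,
                 adjacent_pairs = pairs), class = "stage_design")
}

# stage_design from a SingleCellExperiment with colData$stage
design_from_sce <- function(sce, stages = NULL) {
  st <- SummarizedExperiment::colData(sce)$stage
  stage_design(setNames(as.character(st), colnames(sce)), stages)
}

#' Detect stage-specific features and cluster them by peak stage
#'
#' For every pair of adjacent stages, the log2 fold change of stage-mean
#' normalized expression (pseudocount 1) and a two-sided Wilcoxon rank-sum
#' test on per-cell normalized values are computed per feature. A feature
#' is stage-specific when any adjacent pair shows |logFC| > `logfc_min`
#' and p < `p_max`. Selected features are clustered by the stage of their
#' maximal mean expression; cluster indices follow stage order over the
#' stages that have at least one peaking feature.
#'
#' @param sce SingleCellExperiment with `counts` (and `cpm10`; added if
#'   absent) and colData `stage`
#' @param design optional `stage_design` (default: from colData, stage
#'   order of first appearance)
#' @param logfc_min log2 fold-change threshold (default 1)
#' @param p_max p-value threshold (default 0.01)
#' @return data.frame(feature_id, selected, peak_stage, cluster) with the
#'   per-pair statistics in `attr(, "pairs")`
#' @export
stage_specific_features <- function(sce, design = NULL, logfc_min = 1,
                                    p_max = 0.01) {
  design <- design %||% design_from_sce(sce)
  if (!"cpm10" %in% SummarizedExperiment::assayNames(sce)) {
    sce <- normalize_cpm10(sce)
  }
  x <- as.matrix(SummarizedExperiment::assay(sce, "cpm10"))
  st <- design$cell_stage[colnames(x)]
  stage_means <- vapply(design$stages, function(s)
    rowMeans(x[, st == s, drop = FALSE]), numeric(nrow(x)))
  pair_res <- list()
  selected <- rep(FALSE, nrow(x))
  for (k in seq_len(nrow(design$adjacent_pairs))) {
    s1 <- design$adjacent_pairs[k, 1L]; s2 <- design$adjacent_pairs[k, 2L]
    c1 <- which(st == s1); c2 <- which(st == s2)
    if (length(c1) < 2L || length(c2) < 2L) {
      warning("stage pair ", s1, "-", s2, " skipped: <2 cells")
      next
    }
    lfc <- log2((stage_means[, s2] + 1) / (stage_means[, s1] + 1))
    p <- vapply(seq_len(nrow(x)), function(i) {
      xi <- x[i, c1]; yi <- x[i, c2]
      if (all(xi == xi[1L]) && all(yi == xi[1L])) return(1)
      suppressWarnings(wilcox.test(xi, yi)$p.value)
    }, numeric(1))
    pair_res[[k]] <- data.frame(
      feature_id = rownames(x), pair = paste(s1, s2, sep = "->"),
      logFC = lfc, p_value = p, row.names = NULL)
    selected <- selected | (abs(lfc) > logfc_min & p < p_max)
  }
  peak <- design$stages[apply(stage_means, 1L, which.max)]
  peak_stages <- design$stages[design$stages %in% peak[selected]]
  cluster <- match(peak, peak_stages)
  cluster[!selected] <- NA_integer_
  out <- data.frame(feature_id = rownames(x), selected = selected,
                    peak_stage = peak, cluster = cluster,
                    row.names = NULL)
  attr(out, "pairs") <- do.call(rbind, pair_res)
  attr(out, "n_clusters") <- length(peak_stages)
  out
}

#' Isoform-diversity categories per stage
#'
#' Per stage, every expressed gene is assigned to a category by its number
#' of distinct detected isoforms (1, 2, 3, 4, 5, or >5), pooling the
#' stage's cells.
#'
#' @param sce isoform-level SingleCellExperiment (`counts` assay)
#' @param gene_map data.frame(feature_id, gene_id)
#' @param design optional `stage_design`
#' @return data.frame(stage, category, n_genes, fraction)
#' @export
isoform_diversity <- function(sce, gene_map, design = NULL) {
  design <- design %||% design_from_sce(sce)
  m <- SummarizedExperiment::assay(sce, "counts")
  gene <- gene_map$gene_id[match(rownames(m), gene_map$feature_id)]
  st <- design$cell_stage[colnames(m)]
  cats <- c("1", "2", "3", "4", "5", ">5")
  out <- list()
  for (s in design$stages) {
    sub <- m[, st == s, drop = FALSE]
    iso_detected <- Matrix::rowSums(sub) > 0
    n_iso <- table(gene[iso_detected])
    if (length(n_iso) == 0L) next
    cat_of <- ifelse(n_iso > 5L, ">5", as.character(n_iso))
    tab <- table(factor(cat_of, levels = cats))
    out[[s]] <- data.frame(stage = s, category = cats,
                           n_genes = as.integer(tab),
                           fraction = as.numeric(tab) / sum(tab),
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Major-isoform dominance per gene and stage
#'
#' The major-isoform ratio of a gene is the UMI count of its most abundant
#' isoform divided by the gene's total UMIs, pooling the cells of one
#' stage. Genes at or below `min_umis` total UMIs are excluded.
#'
#' @param sce isoform-level SingleCellExperiment
#' @param gene_map data.frame(feature_id, gene_id)
#' @param design optional `stage_design`
#' @param min_umis exclusive lower bound on gene total UMIs (default 5)
#' @return data.frame(stage, gene_id, total_umis, n_isoforms, major_ratio)
#' @export
major_isoform_ratio <- function(sce, gene_map, design = NULL,
                                min_umis = 5L) {
  design <- design %||% design_from_sce(sce)
  m <- SummarizedExperiment::assay(sce, "counts")
  gene <- gene_map$gene_id[match(rownames(m), gene_map$feature_id)]
  st <- design$cell_stage[colnames(m)]
  out <- list()
  for (s in design$stages) {
    pooled <- Matrix::rowSums(m[, st == s, drop = FALSE])
    tot <- tapply(pooled, gene, sum)
    mx <- tapply(pooled, gene, max)
    ni <- tapply(pooled > 0, gene, sum)
    keep <- tot > min_umis
    if (!any(keep)) next
    out[[s]] <- data.frame(stage = s, gene_id = names(tot)[keep],
                           total_umis = as.integer(tot[keep]),
                           n_isoforms = as.integer(ni[keep]),
                           major_ratio = as.numeric(mx[keep] / tot[keep]),
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Detect isoform switches between two stages
#'
#' For each isoform, the isoform fraction IF = isoform UMIs / gene UMIs is
#' computed on pooled counts per stage, and dIF = IF(stage2) - IF(stage1).
#' The isoform p-value comes from a two-sided exact test on the 2x2 table
#' (isoform UMIs vs other-isoform UMIs across the two stages); the gene
#' p-value is the Bonferroni-adjusted minimum isoform p of the gene. Both
#' sets are BH-adjusted to q-values. An isoform switches when
#' |dIF| >= `dif_min`, isoform q < `q_iso` and gene q < `q_gene`.
#' Genes with fewer than `min_umis` pooled UMIs in either stage are
#' skipped.
#'
#' @param sce isoform-level SingleCellExperiment
#' @param gene_map data.frame(feature_id, gene_id)
#' @param stage_pair character vector of two stage labels
#' @param design optional `stage_design`
#' @param dif_min minimum |dIF| (default 0.1)
#' @param q_iso,q_gene q-value thresholds (defaults 0.05 and 0.01)
#' @param min_umis minimum pooled gene UMIs per stage (default 10)
#' @return data.frame(gene_id, isoform_id, stage1, stage2, if1, if2, dIF,
#'   p_isoform, isoform_q, gene_q, switched); skipped genes in
#'   `attr(, "skipped")`
#' @export
detect_isoform_switch <- function(sce, gene_map, stage_pair, design = NULL,
                                  dif_min = 0.1, q_iso = 0.05,
                                  q_gene = 0.01, min_umis = 10L) {
  stopifnot(length(stage_pair) == 2L)
  design <- design %||% design_from_sce(sce)
  m <- SummarizedExperiment::assay(sce, "counts")
  gene <- gene_map$gene_id[match(rownames(m), gene_map$feature_id)]
  st <- design$cell_stage[colnames(m)]
  n1 <- Matrix::rowSums(m[, st == stage_pair[1L], drop = FALSE])
  n2 <- Matrix::rowSums(m[, st == stage_pair[2L], drop = FALSE])
  g1 <- tapply(n1, gene, sum); g2 <- tapply(n2, gene, sum)
  ok_gene <- names(g1)[g1 >= min_umis & g2 >= min_umis]
  skip_ids <- setdiff(names(g1), ok_gene)
  skipped <- data.frame(
    gene_id = skip_ids,
    reason = rep(sprintf("<%d pooled UMIs in a stage", min_umis),
                 length(skip_ids)))
  keep <- gene %in% ok_gene
  if (!any(keep)) {
    out <- data.frame(gene_id = character(0), isoform_id = character(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  iso <- rownames(m)[keep]; gn <- gene[keep]
  a1 <- n1[keep]; a2 <- n2[keep]
  G1 <- g1[gn]; G2 <- g2[gn]
  if1 <- a1 / G1; if2 <- a2 / G2
  p <- vapply(seq_along(iso), function(i) {
    tab <- matrix(c(a1[i], G1[i] - a1[i], a2[i], G2[i] - a2[i]), nrow = 2L)
    fisher.test(round(tab))$p.value
  }, numeric(1))
  n_iso_gene <- table(gn)
  p_gene_raw <- tapply(p, gn, min)
  p_gene <- setNames(
    pmin(1, p_gene_raw * as.numeric(n_iso_gene[names(p_gene_raw)])),
    names(p_gene_raw))
  q_iso_v <- p.adjust(p, "BH")
  q_gene_v <- p.adjust(p_gene, "BH")[gn]
  out <- data.frame(
    gene_id = gn, isoform_id = iso,
    stage1 = stage_pair[1L], stage2 = stage_pair[2L],
    if1 = as.numeric(if1), if2 = as.numeric(if2),
    dIF = as.numeric(if2 - if1), p_isoform = p,
    isoform_q = q_iso_v, gene_q = as.numeric(q_gene_v),
    switched = abs(if2 - if1) >= dif_min & q_iso_v < q_iso &
      as.numeric(q_gene_v) < q_gene,
    row.names = NULL)
  attr(out, "skipped") <- skipped
  out
}

#' Correlate TE-locus expression with adjacent and distant genes
#'
#' TE loci with mean UMI count above `min_mean_umi` across cells are paired
#' with genes by genomic distance (minimal gap between the TE interval and
#' the gene span; 0 when overlapping; infinite across chromosomes). Pairs
#' closer than `adjacent_max` are `adjacent`; pairs farther than `far_min`
#' (including trans pairs) are `non_adjacent`; others are excluded.
#' Correlation is Pearson on log10(normalized + 1) across the cells shared
#' by both matrices.
#'
#' @param te_sce TE-locus SingleCellExperiment
#' @param gene_sce gene-level SingleCellExperiment
#' @param te_loci TE locus table (locus_id, chrom, start, end)
#' @param genes gene table (gene_id, chrom, start, end)
#' @param min_mean_umi exclusive threshold on TE mean UMIs per cell
#'   (default 5)
#' @param adjacent_max adjacency distance in nt (default 10 kb)
#' @param far_min non-adjacency distance in nt (default 1 Mb)
#' @return data.frame(te_locus_id, gene_id, distance, relation,
#'   correlation, defined)
#' @export
te_gene_correlation <- function(te_sce, gene_sce, te_loci, genes,
                                min_mean_umi = 5, adjacent_max = 10000L,
                                far_min = 1000000L) {
  if (!"cpm10" %in% SummarizedExperiment::assayNames(te_sce)) {
    te_sce <- normalize_cpm10(te_sce)
  }
  if (!"cpm10" %in% SummarizedExperiment::assayNames(gene_sce)) {
    gene_sce <- normalize_cpm10(gene_sce)
  }
  cells <- intersect(colnames(te_sce), colnames(gene_sce))
  tm <- as.matrix(SummarizedExperiment::assay(te_sce, "cpm10"))[, cells,
                                                                drop = FALSE]
  gm <- as.matrix(SummarizedExperiment::assay(gene_sce,
                                              "cpm10"))[, cells,
                                                        drop = FALSE]
  raw <- as.matrix(
    SummarizedExperiment::assay(te_sce, "counts"))[, cells, drop = FALSE]
  active <- rownames(tm)[rowMeans(raw) > min_mean_umi]
  out <- list()
  for (loc in active) {
    li <- te_loci[te_loci$locus_id == loc, ]
    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      if (!g$gene_id %in% rownames(gm)) next
      d <- if (g$chrom != li$chrom) Inf else
        interval_gap(li$start, li$end, g$start, g$end)
      relation <- if (d < adjacent_max) "adjacent"
                  else if (d > far_min) "non_adjacent" else NA_character_
      if (is.na(relation)) next
      x <- log10(tm[loc, ] + 1); y <- log10(gm[g$gene_id, ] + 1)
      defined <- stats::sd(x) > 0 && stats::sd(y) > 0
      out[[length(out) + 1L]] <- data.frame(
        te_locus_id = loc, gene_id = g$gene_id, distance = d,
        relation = relation,
        correlation = if (defined) cor(x, y) else NA_real_,
        defined = defined, row.names = NULL)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(te_locus_id = character(0), gene_id = character(0),
                      distance = numeric(0), relation = character(0),
                      correlation = numeric(0), defined = logical(0)))
  }
  do.call(rbind, out)
}
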