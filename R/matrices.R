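#' Build a single-cell feature matrix
#'
#' Assembles deduplicated molecule counts into a sparse cells-by-feature
#' matrix stored as a [SingleCellExperiment::SingleCellExperiment]
#' (features in rows, cells in columns, per the single-cell container
#' convention). For isoform matrices, features detected in fewer than
#' `min_cells` cells are removed, mirroring the standard low-support
#' isoform filter.
#'
#' @param molecules data.frame(barcode, feature, count) from
#'   [deduplicate_molecules()]
#' @param kind one of `gene`, `isoform`, `te_locus`, `spikein`
#' @param cell_metadata optional data.frame with columns `barcode` and
#'   `stage` (and anything else) attached as colData
#' @param min_cells minimum number of cells a feature must be detected in
#'   (default 5 for isoforms, 1 otherwise)
#' @param feature_metadata optional data.frame with a `feature_id` column
#'   merged into rowData
#' @return a SingleCellExperiment with a `counts` assay
#' @export
build_matrix <- function(molecules, kind = c("gene", "isoform", "te_locus",
                                             "spikein"),
                         cell_metadata = NULL,
                         min_cells = if (kind == "isoform") 5L else 1L,
                         feature_metadata = NULL) {
  kind <- match.arg(kind)
  if (anyDuplicated(molecules[, c("barcode", "feature")])) {
    stop("input error: duplicated (barcode, feature) count entries")
  }
  cells <- sort(unique(molecules$barcode))
  feats <- sort(unique(molecules$feature))
  m <- Matrix::sparseMatrix(
    i = match(molecules$feature, feats),
    j = match(molecules$barcode, cells),
    x = molecules$count, dims = c(length(feats), length(cells)),
    dimnames = list(feats, cells))
  detected <- Matrix::rowSums(m > 0)
  m <- m[detected >= min_cells, , drop = FALSE]
  rd <- S4Vectors::DataFrame(kind = rep(kind, nrow(m)),
                             row.names = rownames(m))
  if (!is.null(feature_metadata)) {
    idx <- match(rownames(m), feature_metadata$feature_id)
    extra <- feature_metadata[idx, setdiff(names(feature_metadata),
                                           "feature_id"), drop = FALSE]
    rd <- cbind(rd, S4Vectors::DataFrame(extra))
  }
  cd <- S4Vectors::DataFrame(row.names = cells)
  if (!is.null(cell_metadata)) {
    idx <- match(cells, cell_metadata$barcode)
    cd <- S4Vectors::DataFrame(
      cell_metadata[idx, setdiff(names(cell_metadata), "barcode"),
                    drop = FALSE], row.names = cells)
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), rowData = rd, colData = cd)
}

#' CPM/10 normalization (copies per 100,000 molecules)
#'
#' Adds a `cpm10` assay: each cell's counts divided by the cell's total
#' deduplicated molecules and scaled to 100,000. Cells with zero total are
#' left at zero with a warning.
#'
#' @param sce a SingleCellExperiment with a `counts` assay
#' @return the SingleCellExperiment with an additional `cpm10` assay
#' @export
normalize_cpm10 <- function(sce) {
  m <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(m)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " cell(s) with zero total molecules left at 0")
  }
  sf <- ifelse(tot == 0, 1, tot)
  cpm <- m %*% Matrix::Diagonal(x = 1e5 / sf)
  dimnames(cpm) <- dimnames(m)
  SummarizedExperiment::assay(sce, "cpm10") <- cpm
  sce
}

#' Per-cell detection statistics
#'
#' @param sce a SingleCellExperiment with a `counts` assay
#' @return data.frame(cell, n_features_detected, n_umis)
#' @export
per_cell_stats <- function(sce) {
  m <- SummarizedExperiment::assay(sce, "counts")
  data.frame(cell = colnames(m),
             n_features_detected = Matrix::colSums(m > 0),
             n_umis = Matrix::colSums(m), row.names = NULL)
}

#' Saturation curve of one cell
#'
#' Subsamples the cell's reads without replacement at each depth (nested
#' subsamples: a random permutation is drawn once and prefixes taken), then
#' deduplicates by UMI and counts distinct features detected. Nested
#' subsampling makes the curve monotone non-decreasing by construction.
#'
#' @param records data.frame(umi, feature) of the cell's reads (one row per
#'   read, duplicates included)
#' @param depths vector of fractions in (0, 1]
#' @param seed integer seed for the permutation
#' @return data.frame(depth, n_reads, n_features)
#' @export
saturation_curve <- function(records, depths, seed = 1L) {
  stopifnot(all(depths > 0), all(depths <= 1))
  set.seed(as.integer(seed %% 2147483647))
  n <- nrow(records)
  perm <- sample.int(n)
  out <- lapply(sort(depths), function(d) {
    k <- max(1L, floor(d * n))
    sub <- records[perm[seq_len(k)], , drop = FALSE]
    data.frame(depth = d, n_reads = k,
               n_features = length(unique(
                 sub$feature[!duplicated(sub[, c("umi", "feature")])])))
  })
  do.call(rbind, out)
}

#' Evaluate spike-in quantification
#'
#' Gene-level: Pearson correlation between log10(true copies per cell + 1)
#' and log10(mean observed UMIs per cell + 1) across spike-in genes.
#' Isoform-level: a confusion matrix of truth versus assigned isoform per
#' molecule, whose off-diagonal counts are mis-assignments.
#'
#' @param sce SingleCellExperiment of spike-in features (isoform-level
#'   counts)
#' @param designs data.frame(transcript_id, copies_per_cell)
#' @param gene_map data.frame(transcript_id, gene_id)
#' @param assignments optional data.frame(truth_isoform, assigned_isoform),
#'   one row per molecule, for the confusion matrix
#' @return a `spikein_evaluation` list: abundance_pairs, correlation
#'   (NA with `correlation_defined = FALSE` if fewer than 3 distinct true
#'   levels), confusion (or NULL)
#' @export
evaluate_spikeins <- function(sce, designs, gene_map, assignments = NULL) {
  m <- SummarizedExperiment::assay(sce, "counts")
  gene_of <- setNames(gene_map$gene_id, gene_map$transcript_id)
  truth_gene <- tapply(designs$copies_per_cell,
                       gene_of[designs$transcript_id], sum)
  obs_iso <- Matrix::rowSums(m) / ncol(m)
  obs_gene <- tapply(obs_iso, gene_of[rownames(m)], sum)
  genes <- names(truth_gene)
  pairs <- data.frame(gene_id = genes,
                      true_copies = as.numeric(truth_gene),
                      observed_umis_per_cell =
                        as.numeric(obs_gene[genes]))
  pairs$observed_umis_per_cell[is.na(pairs$observed_umis_per_cell)] <- 0
  defined <- length(unique(pairs$true_copies)) >= 3L
  r <- if (defined) {
    cor(log10(pairs$true_copies + 1),
        log10(pairs$observed_umis_per_cell + 1), method = "pearson")
  } else NA_real_
  confusion <- NULL
  if (!is.null(assignments)) {
    ids <- sort(unique(c(assignments$truth_isoform,
                         assignments$assigned_isoform)))
    confusion <- table(
      truth = factor(assignments$truth_isoform, levels = ids),
      assigned = factor(assignments$assigned_isoform, levels = ids))
  }
  structure(list(abundance_pairs = pairs, correlation = r,
                 correlation_defined = defined, confusion = confusion),
            class = "spikein_evaluation")
}

#' @export
print.spikein_evaluation <- function(x, ...) {
  cat("spike-in evaluation:", nrow(x$abundance_pairs), "genes; ")
  if (x$correlation_defined) {
    cat(sprintf("log-scale Pearson r = %.3f\n", x$correlation))
  } else {
    cat("correlation undefined (<3 abundance levels)\n")
  }
  if (!is.null(x$confusion)) {
    off <- sum(x$confusion) - sum(diag(x$confusion))
    cat("isoform confusion: ", sum(diag(x$confusion)), " on-diagonal, ",
        off, " off-diagonal\n", sep = "")
  }
  invisible(x)
}

#' Write a matrix as MatrixMarket with TSV sidecars
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` (and a dense
#' `matrix.tsv` when `dense = TRUE`) under a directory.
#'
#' @param sce SingleCellExperiment
#' @param directory output directory
#' @param assay which assay to write
#' @param dense also write a dense TSV (small toys only)
#' @return directory, invisibly
#' @export
write_matrix_dir <- function(sce, directory, assay = "counts",
                             dense = FALSE) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  m <- SummarizedExperiment::assay(sce, assay)
  Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                  file.path(directory, "matrix.mtx"))
  writeLines(rownames(m), file.path(directory, "features.tsv"))
  writeLines(colnames(m), file.path(directory, "barcodes.tsv"))
  if (dense) {
    write.table(as.matrix(m), file.path(directory, "matrix.tsv"),
                sep = "\t", quote = FALSE)
  }
  invisible(directory)
}

#' Read a matrix directory written by [write_matrix_dir()]
#'
#' @param directory directory with matrix.mtx, features.tsv, barcodes.tsv
#' @return a SingleCellExperiment with a `counts` assay
#' @export
read_matrix_dir <- function(directory) {
  m <- Matrix::readMM(file.path(directory, "matrix.mtx"))
  rownames(m) <- readLines(file.path(directory, "features.tsv"))
  colnames(m) <- readLines(file.path(directory, "barcodes.tsv"))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(m, "CsparseMatrix")))
}
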