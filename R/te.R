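#' Build an interval index over TE loci
#'
#' Wraps the rmsk-style locus table in a GenomicRanges index supporting
#' fast overlap queries; results are identical to a linear scan.
#'
#' @param loci data.frame with columns locus_id, chrom, start, end, strand,
#'   rep_name, rep_family, rep_class (0-based half-open coordinates)
#' @return a `te_index` list with `gr` (GRanges) and `loci` (the table)
#' @export
build_te_index <- function(loci) {
  if (anyDuplicated(loci$locus_id)) {
    stop("input error: duplicate TE locus identifiers")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = "*")
  gr$locus_id <- loci$locus_id
  structure(list(gr = gr, loci = loci), class = "te_index")
}

#' Query a TE index with a genomic interval
#'
#' @param index a `te_index`
#' @param chrom chromosome
#' @param start,end 0-based half-open query interval
#' @return the overlapping subset of the locus table
#' @export
query_te_index <- function(index, chrom, start, end) {
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start + 1L, end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, index$gr))
  index$loci[S4Vectors::subjectHits(hits), , drop = FALSE]
}

#' Assign one read to a TE locus
#'
#' Implements locus-level TE read assignment for uniquely aligned reads:
#' (1) non-unique alignments (non-primary, secondary, or mapping quality
#' below `min_mapq`) are rejected; (2) overlap with each candidate locus is
#' the total exon-block intersection; (3) candidates are restricted to loci
#' containing the alignment's genomic start or end position; (4) the locus
#' with the longest overlap wins; (5) ties break deterministically by
#' overlap length, then leftmost locus start, then locus id.
#'
#' @param alignment one row of a [spliced_alignments] data.frame
#' @param index a `te_index`
#' @param min_mapq minimum mapping quality regarded as unique (default 30)
#' @return a one-row data.frame (a `TEAssignment`): read_id, locus_id (NA
#'   if rejected), overlap_length, rejection_reason in
#'   `not_unique`/`no_overlap`/`endpoints_outside`/`none`
#' @export
assign_read_to_te <- function(alignment, index, min_mapq = 30L) {
  assign_reads_to_te(alignment, index, min_mapq = min_mapq)
}

#' Assign many reads to TE loci
#'
#' Vectorised version of [assign_read_to_te()]; one assignment row per
#' input alignment row. Rows flagged as supplementary or secondary, and
#' reads below the mapping-quality threshold, are rejected as `not_unique`.
#'
#' @param alignments a [spliced_alignments] data.frame (primary segments)
#' @param index a `te_index`
#' @param min_mapq minimum mapping quality regarded as unique
#' @return data.frame of `TEAssignment` rows, parallel to `alignments`
#' @export
assign_reads_to_te <- function(alignments, index, min_mapq = 30L) {
  n <- nrow(alignments)
  out <- data.frame(read_id = alignments$read_id,
                    locus_id = NA_character_, overlap_length = 0L,
                    rejection_reason = "none", stringsAsFactors = FALSE)
  unique_ok <- alignments$is_primary & !alignments$is_secondary &
    !alignments$is_supplementary & alignments$mapq >= min_mapq
  out$rejection_reason[!unique_ok] <- "not_unique"
  idx <- which(unique_ok)
  if (length(idx) == 0L) return(out)

  nb <- vapply(alignments$blocks[idx], nrow, integer(1))
  bl <- do.call(rbind, alignments$blocks[idx])
  bl_read <- rep(idx, nb)
  qgr <- GenomicRanges::GRanges(
    rep(alignments$chrom[idx], nb),
    IRanges::IRanges(start = bl[, 1L] + 1L, end = bl[, 2L]))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(qgr, index$gr))
  if (length(hits) == 0L) {
    out$rejection_reason[idx] <- "no_overlap"
    return(out)
  }
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(qgr)[qh], IRanges::ranges(index$gr)[sh]))
  cand <- data.frame(read = bl_read[qh], locus = sh, ov = ov)
  agg <- stats::aggregate(ov ~ read + locus, data = cand, FUN = sum)

  loci <- index$loci
  has_any <- unique(agg$read)
  out$rejection_reason[setdiff(idx, has_any)] <- "no_overlap"

  rs <- alignments$start; re <- alignments$end
  ls <- loci$start[agg$locus]; le <- loci$end[agg$locus]
  p1 <- rs[agg$read]; p2 <- re[agg$read] - 1L
  agg$endpoint_in <- (p1 >= ls & p1 < le) | (p2 >= ls & p2 < le)

  cand2 <- agg[agg$endpoint_in, , drop = FALSE]
  outside <- setdiff(has_any, unique(cand2$read))
  out$rejection_reason[outside] <- "endpoints_outside"
  if (nrow(cand2) > 0L) {
    o <- order(cand2$read, -cand2$ov, loci$start[cand2$locus],
               loci$locus_id[cand2$locus])
    cand2 <- cand2[o, , drop = FALSE]
    best <- cand2[!duplicated(cand2$read), , drop = FALSE]
    out$locus_id[best$read] <- loci$locus_id[best$locus]
    out$overlap_length[best$read] <- best$ov
    out$rejection_reason[best$read] <- "none"
  }
  out
}

#' Build the single-cell TE-locus matrix and rollups
#'
#' Aggregates TE assignments by cell barcode with UMI deduplication into a
#' cell x locus UMI matrix, then sums loci into subfamily (`rep_name`),
#' family (`rep_family`) and class (`rep_class`) rollup matrices. Also
#' reports per-cell expressed-locus counts and, per locus, the mean
#' expression among the cells in which it is active (nonzero).
#'
#' @param assignments data.frame with read_id, locus_id (non-NA rows used),
#'   barcode, umi
#' @param loci the TE locus table (for rollup labels)
#' @param cell_metadata optional data.frame(barcode, stage, ...)
#' @return list with `matrix` (SingleCellExperiment), `rollups` (named list
#'   of dgCMatrix by rep_name/rep_family/rep_class), `per_cell_loci`
#'   (data.frame cell, n_loci_expressed), `per_locus_active_mean`
#' @export
build_te_matrix <- function(assignments, loci, cell_metadata = NULL) {
  a <- assignments[!is.na(assignments$locus_id), , drop = FALSE]
  mol <- deduplicate_molecules(data.frame(
    barcode = a$barcode, umi = a$umi, feature = a$locus_id,
    stringsAsFactors = FALSE))
  meta <- loci[, c("locus_id", "rep_name", "rep_family", "rep_class")]
  names(meta)[1L] <- "feature_id"
  sce <- build_matrix(mol, kind = "te_locus", cell_metadata = cell_metadata,
                      min_cells = 1L, feature_metadata = meta)
  m <- SummarizedExperiment::assay(sce, "counts")
  rd <- SummarizedExperiment::rowData(sce)
  rollups <- lapply(c(rep_name = "rep_name", rep_family = "rep_family",
                      rep_class = "rep_class"), function(col) {
    grp <- as.character(rd[[col]])
    methods::as(rowsum(as.matrix(m), grp), "CsparseMatrix")
  })
  per_cell <- data.frame(cell = colnames(m),
                         n_loci_expressed = Matrix::colSums(m > 0),
                         row.names = NULL)
  active_mean <- data.frame(
    locus_id = rownames(m),
    n_active_cells = Matrix::rowSums(m > 0),
    mean_when_active = ifelse(Matrix::rowSums(m > 0) > 0,
                              Matrix::rowSums(m) /
                                pmax(1, Matrix::rowSums(m > 0)), NA_real_),
    row.names = NULL)
  list(matrix = sce, rollups = rollups, per_cell_loci = per_cell,
       per_locus_active_mean = active_mean)
}

#' Detect TE-gene chimeric transcripts
#'
#' A read is chimeric when it carries two or more alignment segments
#' (primary plus supplementary), one segment is assignable to a TE locus
#' under the unique/endpoint/longest-overlap rules, and a different segment
#' overlaps a protein-coding gene's exons by at least `min_gene_overlap`
#' nt. Links are deduplicated by (barcode, UMI, locus, gene) and
#' aggregated to a TE-locus x gene UMI table.
#'
#' Read names of the form `read_id|barcode|UMI` provide the cell and
#' molecule identity.
#'
#' @param alignments a [spliced_alignments] data.frame (all segments)
#' @param index a `te_index`
#' @param reference a `toy_reference` (or list with `genes`/`exons`
#'   tables); only `protein_coding` genes are linkable
#' @param min_gene_overlap minimum exonic overlap with the gene (nt)
#' @param min_mapq minimum mapping quality per segment
#' @return list with `links` (read-level: read_id, te_locus_id, gene_id,
#'   cell_barcode, umi) and `table` (te_locus_id, gene_id, umi_count)
#' @export
detect_chimeric <- function(alignments, index, reference,
                            min_gene_overlap = 50L, min_mapq = 30L) {
  empty <- list(
    links = data.frame(read_id = character(0), te_locus_id = character(0),
                       gene_id = character(0), cell_barcode = character(0),
                       umi = character(0)),
    table = data.frame(te_locus_id = character(0), gene_id = character(0),
                       umi_count = integer(0)))
  nseg <- table(alignments$read_id)
  multi <- names(nseg)[nseg >= 2L]
  a <- alignments[alignments$read_id %in% multi & !alignments$is_secondary, ,
                  drop = FALSE]
  if (nrow(a) == 0L) return(empty)

  # TE side: apply the locus assignment rules per segment
  seg <- a
  seg$is_primary <- TRUE; seg$is_supplementary <- FALSE
  te_as <- assign_reads_to_te(seg, index, min_mapq = min_mapq)

  # gene side: exonic overlap with protein-coding genes
  pc <- reference$genes$gene_id[reference$genes$biotype == "protein_coding"]
  ex <- reference$exons
  ex <- ex[ex$transcript_id %in%
             reference$transcripts$transcript_id[
               reference$transcripts$gene_id %in% pc], ]
  gene_of_tx <- setNames(reference$transcripts$gene_id,
                         reference$transcripts$transcript_id)
  exg <- GenomicRanges::reduce(GenomicRanges::split(
    GenomicRanges::GRanges(ex$chrom,
                           IRanges::IRanges(ex$start + 1L, ex$end)),
    gene_of_tx[ex$transcript_id]))
  flat <- unlist(exg)
  flat$gene <- rep(names(exg), lengths(exg))
  gene_hit <- rep(NA_character_, nrow(a))
  eligible <- which(a$mapq >= min_mapq)
  if (length(eligible) > 0L) {
    nb <- vapply(a$blocks[eligible], nrow, integer(1))
    bl <- do.call(rbind, a$blocks[eligible])
    qgr <- GenomicRanges::GRanges(
      rep(a$chrom[eligible], nb),
      IRanges::IRanges(bl[, 1L] + 1L, bl[, 2L]))
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(qgr, flat, ignore.strand = TRUE))
    if (length(hits) > 0L) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(qgr)[qh], IRanges::ranges(flat)[sh]))
      df <- data.frame(seg = rep(eligible, nb)[qh],
                       gene = flat$gene[sh], ov = ov)
      agg <- stats::aggregate(ov ~ seg + gene, data = df, FUN = sum)
      agg <- agg[agg$ov >= min_gene_overlap, , drop = FALSE]
      agg <- agg[order(agg$seg, -agg$ov, agg$gene), , drop = FALSE]
      best <- agg[!duplicated(agg$seg), , drop = FALSE]
      gene_hit[best$seg] <- best$gene
    }
  }

  nm <- parse_read_names(a$read_id)
  links <- list()
  for (rid in unique(a$read_id)) {
    rows <- which(a$read_id == rid)
    te_rows <- rows[!is.na(te_as$locus_id[rows])]
    gene_rows <- rows[!is.na(gene_hit[rows])]
    found <- FALSE
    for (ti in te_rows) {
      for (gi in gene_rows) {
        if (ti == gi || found) next
        links[[length(links) + 1L]] <- data.frame(
          read_id = rid, te_locus_id = te_as$locus_id[ti],
          gene_id = gene_hit[gi],
          cell_barcode = nm$barcode[match(rid, a$read_id)],
          umi = nm$umi[match(rid, a$read_id)], stringsAsFactors = FALSE)
        found <- TRUE
      }
    }
  }
  if (length(links) == 0L) return(empty)
  links <- do.call(rbind, links)
  dedup <- links[!duplicated(links[, c("cell_barcode", "umi",
                                       "te_locus_id", "gene_id")]), ]
  tab <- stats::aggregate(
    list(umi_count = dedup$umi),
    by = list(te_locus_id = dedup$te_locus_id, gene_id = dedup$gene_id),
    FUN = length)
  list(links = links, table = tab[order(tab$te_locus_id, tab$gene_id), ])
}

#' Read an rmsk-style TE annotation table
#'
#' Accepts the column subset genoName, genoStart, genoEnd, strand, repName,
#' repClass, repFamily (UCSC rmsk convention, 0-based half-open) and
#' returns the package's locus table with constructed locus ids.
#'
#' @param path TSV file with a header
#' @return data.frame(locus_id, chrom, start, end, strand, rep_name,
#'   rep_family, rep_class)
#' @export
read_rmsk <- function(path) {
  t <- read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(
    chrom = t$genoName, start = t$genoStart, end = t$genoEnd,
    strand = t$strand, rep_name = t$repName, rep_family = t$repFamily,
    rep_class = t$repClass, stringsAsFactors = FALSE)
  out$locus_id <- sprintf("%s:%d-%d:%s", out$chrom, out$start, out$end,
                          out$rep_name)
  out[, c("locus_id", "chrom", "start", "end", "strand", "rep_name",
          "rep_family", "rep_class")]
}

#' Write the TE annotation as an rmsk-style table
#'
#' @param loci locus table (as in `toy_reference$te_loci`)
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_rmsk <- function(loci, path) {
  df <- data.frame(genoName = loci$chrom, genoStart = loci$start,
                   genoEnd = loci$end, strand = loci$strand,
                   repName = loci$rep_name, repClass = loci$rep_class,
                   repFamily = loci$rep_family)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
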