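#' Write a toy reference to standard file formats
#'
#' Writes `genome.fasta`, `genes.gtf` (1-based inclusive, exon features
#' with gene/transcript ids), the TE annotation as both `rmsk.tsv`
#' (UCSC-style columns, 0-based half-open) and `te.bed` (BED6), and
#' `cage_peaks.bed` (BED6). File contents are deterministic for a given
#' reference.
#'
#' @param ref a `toy_reference`
#' @param directory output directory (created if needed)
#' @return named character vector of paths, invisibly
#' @export
write_reference <- function(ref, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- c(
    genome = file.path(directory, "genome.fasta"),
    gtf = file.path(directory, "genes.gtf"),
    rmsk = file.path(directory, "rmsk.tsv"),
    te_bed = file.path(directory, "te.bed"),
    cage = file.path(directory, "cage_peaks.bed"))
  Biostrings::writeXStringSet(ref$genome, paths[["genome"]])
  write_gtf(ref, paths[["gtf"]])
  write_rmsk(ref$te_loci, paths[["rmsk"]])
  te_gr <- GenomicRanges::GRanges(
    ref$te_loci$chrom,
    IRanges::IRanges(ref$te_loci$start + 1L, ref$te_loci$end),
    strand = ref$te_loci$strand)
  te_gr$name <- ref$te_loci$locus_id
  te_gr$score <- 0L
  rtracklayer::export(te_gr, paths[["te_bed"]], format = "BED")
  cage_gr <- GenomicRanges::GRanges(
    ref$cage_peaks$chrom,
    IRanges::IRanges(ref$cage_peaks$start + 1L, ref$cage_peaks$end),
    strand = ref$cage_peaks$strand)
  cage_gr$name <- ref$cage_peaks$name
  cage_gr$score <- 0L
  rtracklayer::export(cage_gr, paths[["cage"]], format = "BED")
  invisible(paths)
}

# GTF export of the gene models (transcript + exon features).
write_gtf <- function(ref, path) {
  ex <- ref$exons
  tx <- ref$transcripts
  gr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end), strand = ex$strand)
  gr$type <- "exon"
  gr$gene_id <- tx$gene_id[match(ex$transcript_id, tx$transcript_id)]
  gr$transcript_id <- ex$transcript_id
  gr$exon_number <- ex$rank
  gr <- gr[order(GenomicRanges::seqnames(gr), GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Imports exon features and reconstructs the package's
#' genes/transcripts/exons tables (0-based half-open internally). CDS
#' coordinates are not part of the exchange format and are set to NA.
#'
#' @param path GTF file
#' @return list with `genes`, `transcripts`, `exons` data.frames in the
#'   `toy_reference` layout
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::import(path, format = "gtf")
  g <- g[g$type == "exon"]
  ex <- data.frame(
    transcript_id = g$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g) - 1L,
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    gene_id = g$gene_id, stringsAsFactors = FALSE)
  ex <- ex[order(ex$transcript_id, ex$start), ]
  rank <- stats::ave(seq_len(nrow(ex)), ex$transcript_id, FUN = seq_along)
  minus <- ex$strand == "-"
  # transcript rank runs 5'->3'
  n_per <- stats::ave(seq_len(nrow(ex)), ex$transcript_id, FUN = length)
  ex$rank <- ifelse(minus, n_per - rank + 1L, rank)
  tx <- unique(ex[, c("transcript_id", "gene_id", "chrom", "strand")])
  tx$cds_start <- NA_integer_; tx$cds_end <- NA_integer_
  genes <- do.call(rbind, lapply(unique(ex$gene_id), function(gid) {
    e <- ex[ex$gene_id == gid, ]
    data.frame(gene_id = gid, chrom = e$chrom[1L], strand = e$strand[1L],
               start = min(e$start), end = max(e$end),
               biotype = "protein_coding", stringsAsFactors = FALSE)
  }))
  list(genes = genes, transcripts = as.data.frame(tx),
       exons = ex[, c("transcript_id", "rank", "chrom", "start", "end",
                      "strand")])
}

#' Read CAGE peaks from a BED file
#'
#' @param path BED6 file
#' @return data.frame(chrom, start, end, strand, name), 0-based half-open
#' @export
read_cage_bed <- function(path) {
  g <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g) - 1L,
             end = GenomicRanges::end(g),
             strand = as.character(GenomicRanges::strand(g)),
             name = if (!is.null(g$name)) g$name else NA_character_,
             stringsAsFactors = FALSE)
}

#' Run the full pipeline on simulator output
#'
#' Convenience driver for tests and examples: routes single-segment truth
#' alignments to gene assignment, isoform collapse and TE assignment,
#' multi-segment reads to chimera detection, deduplicates molecules, and
#' returns the gene, isoform and TE matrices together with the collapsed
#' isoform models and chimera table.
#'
#' @param sim an `sc_simulation`
#' @param ref the `toy_reference` it was simulated from
#' @param isoform_min_cells isoform matrix cell filter (default 5)
#' @return list with `gene_sce`, `isoform_sce`, `isoforms` (classified
#'   models), `isoform_gene_map`, `te` (output of [build_te_matrix()]),
#'   `chimera` (output of [detect_chimeric()])
#' @export
run_toy_pipeline <- function(sim, ref, isoform_min_cells = 5L) {
  al <- sim$alignments
  nm <- parse_read_names(al$read_id)
  nseg <- table(al$read_id)
  single <- al[al$read_id %in% names(nseg)[nseg == 1L], , drop = FALSE]
  nm1 <- parse_read_names(single$read_id)
  cell_meta <- sim$design$cells[, c("barcode", "stage")]

  # gene-level matrix
  gene <- assign_to_genes(single, ref)
  okg <- !is.na(gene)
  gene_mol <- deduplicate_molecules(data.frame(
    barcode = nm1$barcode[okg], umi = nm1$umi[okg], feature = gene[okg]))
  gene_sce <- build_matrix(gene_mol, "gene", cell_metadata = cell_meta)
  gene_sce <- normalize_cpm10(gene_sce)

  # isoform-level matrix via collapse
  iso <- collapse_isoforms(single)
  iso <- classify_structural(iso, ref)
  keep <- iso$structural_class %in% c("FSM", "ISM", "NIC", "NNC")
  iso_keep <- iso[keep, , drop = FALSE]
  read_iso <- data.frame(
    read_id = unlist(iso_keep$support),
    isoform = rep(iso_keep$isoform_id, lengths(iso_keep$support)))
  nmi <- parse_read_names(read_iso$read_id)
  iso_mol <- deduplicate_molecules(data.frame(
    barcode = nmi$barcode, umi = nmi$umi, feature = read_iso$isoform))
  iso_sce <- build_matrix(iso_mol, "isoform", cell_metadata = cell_meta,
                          min_cells = isoform_min_cells)
  iso_sce <- normalize_cpm10(iso_sce)
  gene_map <- data.frame(feature_id = iso_keep$isoform_id,
                         gene_id = iso_keep$assigned_gene)

  # TE quantification
  te_index <- build_te_index(ref$te_loci)
  te_as <- assign_reads_to_te(single, te_index)
  te_as$barcode <- nm1$barcode; te_as$umi <- nm1$umi
  te <- build_te_matrix(te_as, ref$te_loci, cell_metadata = cell_meta)

  # chimeric transcripts
  chim <- detect_chimeric(al, te_index, ref)

  list(gene_sce = gene_sce, isoform_sce = iso_sce, isoforms = iso,
       isoform_gene_map = gene_map, te = te, chimera = chim)
}
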