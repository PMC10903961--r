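#' Build a toy reference for simulation and testing
#'
#' Generates a small genome with annotated multi-isoform gene models,
#' RepeatMasker-style transposable-element (TE) loci, CAGE peaks at
#' transcription start sites, and optional spike-in transcripts, emulating in
#' miniature the reference objects a long-read single-cell pipeline consumes
#' (genome FASTA, gene GTF, rmsk table, CAGE BED).
#'
#' Design of the gene models: each gene's full-length transcript carries one
#' open reading frame (ATG + stop-free codon body + stop codon) flanked by
#' short UTRs. Exon boundaries inside the coding region are codon-aligned and
#' internal exons are fully coding, so exon-skipping isoforms keep an intact
#' reading frame. The codon body contains a recurring 9-mer whose two shifted
#' reading frames hit stop codons, so no spurious long ORF can outcompete the
#' annotated one. A gene has 1-6 isoforms differing by internal exon
#' skipping; all share the TSS and the terminal exon.
#'
#' TE loci are drawn from a small class/family/subfamily hierarchy
#' (LINE/L1, LTR/ERVL and ERVK, SINE, DNA, Satellite). A fraction
#' `te_near_frac` is placed in intergenic gaps of the gene chromosomes
#' (within 10 kb of a gene); the remainder is placed on a dedicated gene-free
#' chromosome, so that those loci are unlinked to every gene (the
#' "non-adjacent" category of TE-gene correlation analyses).
#'
#' @param seed integer seed; the builder is deterministic given the seed
#' @param n_chromosomes number of gene-bearing chromosomes
#' @param n_genes total number of genes (>= 1), distributed round-robin
#' @param n_te_loci total number of TE loci (>= 1)
#' @param chrom_length length of each gene chromosome in nt (50-500 kb)
#' @param te_near_frac fraction of TE loci placed within 10 kb of a gene
#' @param n_spikein_genes number of spike-in genes on a dedicated spike
#'   chromosome (0 disables); gene-level true copies per cell double per gene
#'   starting at `spikein_base_copies`
#' @param spikein_base_copies copies per cell of the least abundant spike-in
#' @param gap_range intergenic gap length range in nt; wide gaps (e.g.
#'   ~20 kb) guarantee that a gene-adjacent TE locus lies within 10 kb of
#'   exactly one gene
#' @return an object of class `toy_reference`: a list with `genome`
#'   (DNAStringSet), `genes`, `transcripts`, `exons` (0-based half-open
#'   genomic coordinates, `rank` in transcript 5'->3' order), `te_loci`,
#'   `cage_peaks`, `spikein_designs`, and `params`
#' @export
build_toy_reference <- function(seed, n_chromosomes = 1L, n_genes = 5L,
                                n_te_loci = 20L, chrom_length = 200000L,
                                te_near_frac = 0.5, n_spikein_genes = 0L,
                                spikein_base_copies = 2,
                                gap_range = c(4000L, 8000L)) {
  stopifnot(n_genes >= 1L, n_te_loci >= 1L, n_chromosomes >= 1L)
  set.seed(as.integer(seed %% 2147483647))

  chroms <- paste0("chr", seq_len(n_chromosomes))
  genes <- list(); transcripts <- list(); exons <- list()
  gene_seqs <- list()   # per gene: list(chrom, start, seq)
  gaps <- list()        # intergenic gaps available for near TEs
  gene_per_chrom <- table(factor(rep(chroms, length.out = n_genes),
                                 levels = chroms))

  gidx <- 0L
  for (ci in seq_along(chroms)) {
    cursor <- sample(3000:6000, 1L)
    for (k in seq_len(gene_per_chrom[[ci]])) {
      gidx <- gidx + 1L
      g <- make_toy_gene(sprintf("G%03d", gidx), chroms[ci], cursor)
      if (g$end > chrom_length - 2000L) {
        stop("sizing error: chromosome ", chroms[ci], " (", chrom_length,
             " nt) too small for the requested gene models")
      }
      genes[[gidx]] <- g$gene
      transcripts[[gidx]] <- g$transcripts
      exons[[gidx]] <- g$exons
      gene_seqs[[gidx]] <- list(chrom = chroms[ci], start = g$start,
                                seq = g$seq)
      gap_len <- sample(gap_range[1L]:gap_range[2L], 1L)
      gaps[[length(gaps) + 1L]] <- list(chrom = chroms[ci],
                                        start = g$end + 200L,
                                        end = g$end + gap_len - 200L)
      cursor <- g$end + gap_len
    }
  }
  genes <- do.call(rbind, genes)
  transcripts <- do.call(rbind, transcripts)
  exons <- do.call(rbind, exons)

  # ---- TE loci ------------------------------------------------------------
  fam <- te_hierarchy()
  n_near <- round(n_te_loci * te_near_frac)
  n_far <- n_te_loci - n_near
  pick <- fam[sample(nrow(fam), n_te_loci, replace = TRUE), ]
  te_len <- as.integer(round(runif(n_te_loci, pick$len_min, pick$len_max)))
  te <- data.frame(chrom = NA_character_, start = NA_integer_,
                   end = NA_integer_,
                   strand = sample(c("+", "-"), n_te_loci, replace = TRUE),
                   rep_name = pick$rep_name, rep_family = pick$rep_family,
                   rep_class = pick$rep_class, stringsAsFactors = FALSE)
  gap_cursor <- vapply(gaps, function(g) g$start, numeric(1))
  gap_end <- vapply(gaps, function(g) g$end, numeric(1))
  for (i in seq_len(n_near)) {
    ok <- which(gap_end - gap_cursor > te_len[i] + 100L)
    if (length(ok) == 0L) {
      stop("sizing error: not enough intergenic space for ", n_near,
           " gene-adjacent TE loci")
    }
    j <- if (length(ok) == 1L) ok else sample(ok, 1L)
    s <- as.integer(gap_cursor[j] + sample(0:50, 1L))
    te$chrom[i] <- gaps[[j]]$chrom
    te$start[i] <- s
    te$end[i] <- s + te_len[i]
    gap_cursor[j] <- s + te_len[i] + 100L
  }
  chrU_len <- 0L
  if (n_far > 0L) {
    chrU_len <- as.integer(min(500000L, max(50000L, n_far * 3000L + 10000L)))
    if (n_far * 3000L + 10000L > 500000L) {
      stop("sizing error: too many gene-distal TE loci for one chromosome")
    }
    cur <- 2000L
    for (i in n_near + seq_len(n_far)) {
      te$chrom[i] <- "chrU"
      te$start[i] <- cur + sample(0:500, 1L)
      te$end[i] <- te$start[i] + te_len[i]
      cur <- te$end[i] + sample(500:1500, 1L)
    }
    if (max(te$end[te$chrom == "chrU"]) > chrU_len - 1000L) {
      chrU_len <- as.integer(max(te$end[te$chrom == "chrU"]) + 2000L)
    }
  }
  te$locus_id <- sprintf("%s:%d-%d:%s", te$chrom, te$start, te$end,
                         te$rep_name)
  stopifnot(!anyDuplicated(te$locus_id))
  te <- te[, c("locus_id", "chrom", "start", "end", "strand",
               "rep_name", "rep_family", "rep_class")]

  # ---- spike-ins ----------------------------------------------------------
  spike_designs <- data.frame(transcript_id = character(0),
                              copies_per_cell = numeric(0))
  chrS_len <- 0L
  if (n_spikein_genes > 0L) {
    cursor <- 2000L
    copies_gene <- spikein_base_copies * 2^(seq_len(n_spikein_genes) - 1L)
    for (k in seq_len(n_spikein_genes)) {
      gidx <- gidx + 1L
      g <- make_toy_gene(sprintf("SPIKE%02d", k), "chrS", cursor,
                         biotype = "spikein")
      genes <- rbind(genes, g$gene)
      transcripts <- rbind(transcripts, g$transcripts)
      exons <- rbind(exons, g$exons)
      gene_seqs[[length(gene_seqs) + 1L]] <-
        list(chrom = "chrS", start = g$start, seq = g$seq)
      iso <- g$transcripts$transcript_id
      per_iso <- pmax(1, round(copies_gene[k] / length(iso)))
      spike_designs <- rbind(spike_designs, data.frame(
        transcript_id = iso, copies_per_cell = per_iso))
      cursor <- g$end + sample(3000:5000, 1L)
    }
    chrS_len <- as.integer(cursor + 2000L)
  }

  # ---- genome assembly ----------------------------------------------------
  all_chroms <- c(setNames(rep(chrom_length, n_chromosomes), chroms),
                  if (chrU_len > 0L) c(chrU = chrU_len),
                  if (chrS_len > 0L) c(chrS = chrS_len))
  genome <- lapply(names(all_chroms),
                   function(cn) random_dna(1L, all_chroms[[cn]]))
  names(genome) <- names(all_chroms)
  for (gs in gene_seqs) {
    substr(genome[[gs$chrom]], gs$start + 1L,
           gs$start + nchar(gs$seq)) <- gs$seq
  }
  genome <- Biostrings::DNAStringSet(unlist(genome))

  # ---- CAGE peaks: one per gene TSS plus decoys ---------------------------
  tss <- gene_tss(transcripts, exons)
  decoy_n <- max(2L, round(nrow(genes) / 3))
  decoys <- data.frame(
    chrom = sample(chroms, decoy_n, replace = TRUE),
    start = sample(1000:(chrom_length - 1000L), decoy_n),
    strand = sample(c("+", "-"), decoy_n, replace = TRUE))
  cage <- rbind(
    data.frame(chrom = tss$chrom, start = pmax(0L, tss$tss - 20L),
               end = tss$tss + 20L, strand = tss$strand,
               name = paste0("peak_", tss$gene_id)),
    data.frame(chrom = decoys$chrom, start = decoys$start,
               end = decoys$start + 40L, strand = decoys$strand,
               name = paste0("decoy_", seq_len(decoy_n))))

  ref <- list(genome = genome, genes = genes, transcripts = transcripts,
              exons = exons, te_loci = te, cage_peaks = cage,
              spikein_designs = spike_designs,
              params = list(seed = seed, n_chromosomes = n_chromosomes,
                            n_genes = n_genes, n_te_loci = n_te_loci,
                            chrom_length = chrom_length))
  class(ref) <- "toy_reference"
  ref
}

# Safe codons for the ORF body: no start, no stop.
safe_codons <- function() {
  all <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES,
                         paste0))
  setdiff(all, c("ATG", "TAA", "TAG", "TGA"))
}

# Remove ATG trigrams from a DNA string (any frame).
scrub_atg <- function(x) {
  while (grepl("ATG", x, fixed = TRUE)) x <- sub("ATG", "ACG", x, fixed = TRUE)
  x
}

# Build one gene: transcript design, exon/intron layout, isoforms.
# Returns gene/transcript/exon tables plus the genomic sequence segment.
make_toy_gene <- function(gene_id, chrom, gstart, biotype = "protein_coding") {
  n_codons <- sample(220:320, 1L)
  u5 <- sample(30:60, 1L)
  u3 <- sample(90:150, 1L)
  body <- sample(safe_codons(), n_codons, replace = TRUE)
  # recurring block whose +1/+2 frames contain stops, capping off-frame ORFs
  blk <- c("CTA", "ACT", "AGC")
  at <- seq(15L, n_codons - 3L, by = 18L)
  for (p in at) body[p:(p + 2L)] <- blk
  orf <- paste0("ATG", paste0(body, collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1L))
  tx_seq <- paste0(scrub_atg(random_dna(1L, u5)), orf, random_dna(1L, u3))
  L <- nchar(tx_seq)
  cds_start <- u5
  cds_end <- u5 + nchar(orf)        # half-open, includes stop codon

  n_ex <- sample(3:6, 1L)
  cand <- seq(u5 + 45L + (3L - (45L %% 3L)) %% 3L, L - u3 - 45L, by = 3L)
  cand <- cand[(cand - u5) %% 3L == 0L]
  repeat {
    cuts <- sort(sample(cand, n_ex - 1L))
    if (min(diff(c(0L, cuts, L))) >= 60L) break
  }
  ex_tx_start <- c(0L, cuts)
  ex_tx_end <- c(cuts, L)
  ex_len <- ex_tx_end - ex_tx_start
  intron_len <- sample(200:800, n_ex - 1L, replace = TRUE)

  # genomic layout in transcript orientation
  seg_parts <- character(2L * n_ex - 1L)
  ex_seg_start <- integer(n_ex)
  pos <- 0L
  for (i in seq_len(n_ex)) {
    ex_seg_start[i] <- pos
    seg_parts[2L * i - 1L] <- substr(tx_seq, ex_tx_start[i] + 1L,
                                     ex_tx_end[i])
    pos <- pos + ex_len[i]
    if (i < n_ex) {
      seg_parts[2L * i] <- random_dna(1L, intron_len[i])
      pos <- pos + intron_len[i]
    }
  }
  seg <- paste0(seg_parts, collapse = "")
  seg_len <- nchar(seg)
  strand <- sample(c("+", "-"), 1L)
  if (strand == "-") {
    seg <- revcomp(seg)
    ex_gstart <- gstart + seg_len - (ex_seg_start + ex_len)
    ex_gend <- gstart + seg_len - ex_seg_start
  } else {
    ex_gstart <- gstart + ex_seg_start
    ex_gend <- gstart + ex_seg_start + ex_len
  }

  # isoforms: full chain first, then internal-exon skips
  internal <- if (n_ex > 2L) 2:(n_ex - 1L) else integer(0)
  subsets <- list(integer(0))
  for (k in seq_along(internal)) {
    idx <- utils::combn(seq_along(internal), k, simplify = FALSE)
    subsets <- c(subsets, lapply(idx, function(j) internal[j]))
  }
  # keep >=150 coding codons in every isoform so truncation points can be
  # sampled inside the ORF of any isoform
  subsets <- subsets[vapply(subsets, function(s) sum(ex_len[s]), 0) <=
                       (cds_end - cds_start) - 450L]
  n_iso <- min(sample(1:6, 1L), length(subsets))
  keep_sets <- c(subsets[1L],
                 if (n_iso > 1L) sample(subsets[-1L], n_iso - 1L))

  tx <- list(); exn <- list()
  for (i in seq_len(n_iso)) {
    skip <- keep_sets[[i]]
    kept <- setdiff(seq_len(n_ex), skip)
    tid <- paste0(gene_id, ".", i)
    cds_len <- (cds_end - cds_start) - sum(ex_len[skip])
    tx[[i]] <- data.frame(
      transcript_id = tid, gene_id = gene_id, chrom = chrom,
      strand = strand, cds_start = cds_start,
      cds_end = cds_start + cds_len, stringsAsFactors = FALSE)
    exn[[i]] <- data.frame(
      transcript_id = tid, rank = seq_along(kept), chrom = chrom,
      start = ex_gstart[kept], end = ex_gend[kept], strand = strand,
      stringsAsFactors = FALSE)
  }
  list(
    gene = data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      start = gstart, end = gstart + seg_len,
                      biotype = biotype, stringsAsFactors = FALSE),
    transcripts = do.call(rbind, tx),
    exons = do.call(rbind, exn),
    start = gstart, end = gstart + seg_len, seq = seg)
}

te_hierarchy <- function() {
  data.frame(
    rep_class = c("LINE", "LINE", "LTR", "LTR", "LTR", "SINE", "SINE",
                  "DNA", "Satellite"),
    rep_family = c("L1", "L1", "ERVL", "ERVL", "ERVK", "B1", "B2",
                   "TcMar-Tigger", "Satellite"),
    rep_name = c("Lx7", "L1Md_T", "MERVL-int", "MT2_mm", "IAPEz-int",
                 "B1_Mus1", "B2_Mm2", "Tigger1", "GSAT_MM"),
    len_min = c(500, 700, 400, 300, 500, 120, 150, 200, 300),
    len_max = c(1500, 1500, 900, 600, 1200, 300, 350, 600, 800),
    stringsAsFactors = FALSE)
}

# TSS (genomic position of the transcript 5' end) per gene; all isoforms of a
# toy gene share exon 1, so the first transcript suffices.
gene_tss <- function(transcripts, exons) {
  first_tx <- transcripts[!duplicated(transcripts$gene_id), ]
  tss <- integer(nrow(first_tx))
  for (i in seq_len(nrow(first_tx))) {
    ex <- exons[exons$transcript_id == first_tx$transcript_id[i], ]
    ex <- ex[order(ex$rank), ]
    tss[i] <- if (first_tx$strand[i] == "+") ex$start[1L] else ex$end[1L] - 1L
  }
  data.frame(gene_id = first_tx$gene_id, chrom = first_tx$chrom,
             strand = first_tx$strand, tss = tss)
}

#' Extract transcript sequences from a toy reference
#'
#' Concatenates the exon sequences of each transcript in 5'->3' transcript
#' orientation (reverse-complemented for minus-strand models).
#'
#' @param ref a `toy_reference`
#' @param transcript_ids transcripts to extract (default: all)
#' @return named character vector of transcript sequences
#' @export
transcript_sequences <- function(ref, transcript_ids = NULL) {
  ids <- transcript_ids %||% unique(ref$transcripts$transcript_id)
  chrom_chr <- as.character(ref$genome)
  out <- character(length(ids))
  for (i in seq_along(ids)) {
    ex <- ref$exons[ref$exons$transcript_id == ids[i], ]
    ex <- ex[order(ex$start), ]
    parts <- substring(chrom_chr[[ex$chrom[1L]]], ex$start + 1L, ex$end)
    s <- paste0(parts, collapse = "")
    if (ex$strand[1L] == "-") s <- revcomp(s)
    out[i] <- s
  }
  names(out) <- ids
  out
}

#' Exon blocks of annotated transcripts
#'
#' @param ref a `toy_reference` (or any list with an `exons` table)
#' @param transcript_id one transcript
#' @return two-column matrix of 0-based half-open exon intervals in genomic
#'   order
#' @export
transcript_blocks <- function(ref, transcript_id) {
  ex <- ref$exons[ref$exons$transcript_id == transcript_id, ]
  ex <- ex[order(ex$start), ]
  cbind(start = ex$start, end = ex$end)
}

#' Validate toy-reference invariants
#'
#' Checks that all annotated intervals lie within chromosome bounds, exons of
#' each transcript are non-overlapping, annotated CDS sequences begin with a
#' start codon and end with a stop codon, and TE locus identifiers are
#' unique. Called for its side effect; errors on violation.
#'
#' @param ref a `toy_reference`
#' @return `TRUE`, invisibly
#' @export
validate_toy_reference <- function(ref) {
  lens <- Biostrings::width(ref$genome)
  names(lens) <- names(ref$genome)
  in_bounds <- function(chrom, start, end) {
    all(start >= 0L & end <= lens[chrom] & end > start)
  }
  stopifnot(in_bounds(ref$exons$chrom, ref$exons$start, ref$exons$end),
            in_bounds(ref$te_loci$chrom, ref$te_loci$start, ref$te_loci$end),
            in_bounds(ref$cage_peaks$chrom, ref$cage_peaks$start,
                      ref$cage_peaks$end),
            !anyDuplicated(ref$te_loci$locus_id))
  for (tid in unique(ref$exons$transcript_id)) {
    ex <- ref$exons[ref$exons$transcript_id == tid, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1L) stopifnot(all(ex$start[-1L] >= ex$end[-nrow(ex)]))
  }
  seqs <- transcript_sequences(ref)
  for (i in seq_len(nrow(ref$transcripts))) {
    tr <- ref$transcripts[i, ]
    s <- seqs[[tr$transcript_id]]
    stopifnot(substr(s, tr$cds_start + 1L, tr$cds_start + 3L) == "ATG",
              substr(s, tr$cds_end - 2L, tr$cds_end) %in%
                c("TAA", "TAG", "TGA"))
  }
  invisible(TRUE)
}

#' @export
print.toy_reference <- function(x, ...) {
  cat("toy_reference:",
      length(x$genome), "chromosomes,",
      nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,",
      nrow(x$te_loci), "TE loci,",
      nrow(x$cage_peaks), "CAGE peaks\n")
  invisible(x)
}
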