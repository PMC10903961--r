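#' Describe a simulated single-cell experiment
#'
#' Encodes the study conditions of a stage-structured single-cell long-read
#' experiment: ordered developmental stages, cells per stage, the expected
#' molecule count per (stage, feature) for gene isoforms and TE loci,
#' planted stage-specific features, planted isoform switches, per-stage
#' truncation rates, TE-gene chimera pairs, and spike-ins.
#'
#' Defaults emulate the biology the pipeline targets: maternal transcripts
#' truncated at the 3' end are frequent in oocytes and zygotes (rate 0.25)
#' and rare afterwards (0.05); 5'-partial molecules (incomplete reverse
#' transcription) occur at 0.05 and internal fragments at 0.02 in all
#' stages; PCR duplicates are emitted at rate 0.2.
#'
#' @param reference a `toy_reference`
#' @param stages ordered character vector of stage labels
#' @param cells_per_stage cells per stage
#' @param seed integer seed for molecule sampling
#' @param base_isoform_mean mean of the per-isoform baseline expected
#'   molecule count (per cell)
#' @param base_te_mean baseline expected molecules per TE locus per cell
#' @param planted_stage_specific data.frame(feature_id, peak_stage, fold)
#'   of features whose expectation is multiplied by `fold` in their peak
#'   stage; feature ids may be isoform ids or TE locus ids
#' @param planted_switches data.frame(gene_id, isoform_a, isoform_b,
#'   boundary) where `boundary` is the index of the last stage before the
#'   switch; isoform_a carries fraction `switch_hi` of the gene before the
#'   boundary and `1 - switch_hi` after (isoform_b mirrored)
#' @param switch_hi major-isoform fraction on the high side of a switch
#' @param truncation_rates data.frame with columns stage, p3, p5, p_internal
#' @param chimera_pairs data.frame(te_locus, gene_id, expected) expected
#'   chimeric molecules per cell
#' @param include_spikeins add spike-in molecules at the reference's design
#'   copies
#' @param dup_rate expected PCR duplicates per molecule (Poisson)
#' @param error_rate per-base substitution rate applied to reads
#' @param bc_len,umi_len barcode and UMI lengths (nt)
#' @param primer_5,primer_3 primer sequences flanking the insert
#' @param polya_len length of the appended polyA tail
#' @return an object of class `experiment_design`
#' @export
experiment_design <- function(reference,
                              stages = c("oocyte", "zygote", "E2C", "L2C",
                                         "C4", "C8", "blastocyst", "mESC"),
                              cells_per_stage = 4L,
                              seed = 1L,
                              base_isoform_mean = 2,
                              base_te_mean = 1,
                              planted_stage_specific = NULL,
                              planted_switches = NULL,
                              switch_hi = 0.9,
                              truncation_rates = NULL,
                              chimera_pairs = NULL,
                              include_spikeins = FALSE,
                              dup_rate = 0.2,
                              error_rate = 0,
                              bc_len = 16L, umi_len = 10L,
                              primer_5 = "AAGCAGTGGTATCAACGCAGAGT",
                              primer_3 = "CATGTAGCCGATTCAGGCCATTCA",
                              polya_len = 25L) {
  stopifnot(length(stages) >= 1L, cells_per_stage >= 1L)
  set.seed(as.integer(child_seed(seed, 17L)))

  iso <- reference$transcripts[
    reference$transcripts$gene_id %in%
      reference$genes$gene_id[reference$genes$biotype == "protein_coding"], ]
  features <- data.frame(
    feature_id = c(iso$transcript_id, reference$te_loci$locus_id),
    kind = c(rep("isoform", nrow(iso)), rep("te_locus",
                                            nrow(reference$te_loci))),
    gene_id = c(iso$gene_id, rep(NA_character_, nrow(reference$te_loci))),
    stringsAsFactors = FALSE)

  base <- c(pmin(8, pmax(0.5, stats::rlnorm(nrow(iso),
                                            log(base_isoform_mean), 0.6))),
            pmin(4, pmax(0.3, stats::rlnorm(nrow(reference$te_loci),
                                            log(base_te_mean), 0.5))))
  lambda <- matrix(rep(base, length(stages)), ncol = length(stages),
                   dimnames = list(features$feature_id, stages))

  if (!is.null(planted_stage_specific)) {
    stopifnot(all(planted_stage_specific$feature_id %in%
                    features$feature_id),
              all(planted_stage_specific$peak_stage %in% stages))
    for (i in seq_len(nrow(planted_stage_specific))) {
      p <- planted_stage_specific[i, ]
      lambda[p$feature_id, p$peak_stage] <-
        lambda[p$feature_id, p$peak_stage] * p$fold
    }
  }
  if (!is.null(planted_switches)) {
    stopifnot(all(planted_switches$isoform_a %in% features$feature_id),
              all(planted_switches$isoform_b %in% features$feature_id))
    for (i in seq_len(nrow(planted_switches))) {
      sw <- planted_switches[i, ]
      tot <- lambda[sw$isoform_a, ] + lambda[sw$isoform_b, ]
      pre <- seq_along(stages) <= sw$boundary
      lambda[sw$isoform_a, ] <- ifelse(pre, switch_hi, 1 - switch_hi) * tot
      lambda[sw$isoform_b, ] <- ifelse(pre, 1 - switch_hi, switch_hi) * tot
    }
  }
  if (is.null(truncation_rates)) {
    truncation_rates <- data.frame(
      stage = stages,
      p3 = ifelse(seq_along(stages) <= 2L, 0.25, 0.05),
      p5 = 0.05, p_internal = 0.02)
  }
  stopifnot(all(truncation_rates$p3 >= 0 & truncation_rates$p3 <= 1),
            all(truncation_rates$p5 >= 0 & truncation_rates$p5 <= 1),
            all(lambda >= 0))
  if (!is.null(chimera_pairs)) {
    stopifnot(all(chimera_pairs$te_locus %in% reference$te_loci$locus_id),
              all(chimera_pairs$gene_id %in% reference$genes$gene_id))
  }

  n_cells <- length(stages) * cells_per_stage
  cells <- data.frame(
    cell_id = sprintf("cell%03d", seq_len(n_cells)),
    barcode = make_whitelist(n_cells, bc_len, min_dist = 3L),
    stage = rep(stages, each = cells_per_stage),
    stringsAsFactors = FALSE)

  structure(list(
    stages = stages, cells_per_stage = cells_per_stage, cells = cells,
    features = features, expression_program = lambda,
    planted_stage_specific = planted_stage_specific,
    planted_switches = planted_switches, switch_hi = switch_hi,
    truncation_rates = truncation_rates, chimera_pairs = chimera_pairs,
    include_spikeins = include_spikeins, dup_rate = dup_rate,
    error_rate = error_rate, bc_len = bc_len, umi_len = umi_len,
    primer_5 = primer_5, primer_3 = primer_3, polya_len = polya_len,
    seed = seed), class = "experiment_design")
}

#' Generate a barcode whitelist with a minimum pairwise Hamming distance
#'
#' @param n number of barcodes
#' @param len barcode length
#' @param min_dist minimum pairwise Hamming distance (3 guarantees that
#'   single-substitution errors have a unique distance-1 neighbour)
#' @return character vector of barcodes
#' @export
make_whitelist <- function(n, len = 16L, min_dist = 3L) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_dna(n, len)
    for (b in cand) {
      if (length(out) >= n) break
      if (length(out) == 0L || min(hamming(rep(b, length(out)), out)) >=
            min_dist) {
        out <- c(out, b)
      }
    }
  }
  out
}

# Map a transcript-coordinate interval [s, e) to genomic exon blocks.
# tx_map: data.frame(tx_start, tx_end, g_start, g_end) in transcript order.
tx_interval_to_blocks <- function(tx_map, s, e, strand) {
  hit <- tx_map[tx_map$tx_end > s & tx_map$tx_start < e, , drop = FALSE]
  bl <- matrix(0, nrow = nrow(hit), ncol = 2L)
  for (j in seq_len(nrow(hit))) {
    x <- max(s, hit$tx_start[j]); y <- min(e, hit$tx_end[j])
    if (strand == "+") {
      bl[j, ] <- c(hit$g_start[j] + (x - hit$tx_start[j]),
                   hit$g_start[j] + (y - hit$tx_start[j]))
    } else {
      bl[j, ] <- c(hit$g_end[j] - (y - hit$tx_start[j]),
                   hit$g_end[j] - (x - hit$tx_start[j]))
    }
  }
  bl <- bl[order(bl[, 1L]), , drop = FALSE]
  storage.mode(bl) <- "integer"
  colnames(bl) <- c("start", "end")
  bl
}

# Per-transcript map from transcript coordinates to genomic exons.
build_tx_maps <- function(ref) {
  maps <- list()
  for (tid in unique(ref$exons$transcript_id)) {
    ex <- ref$exons[ref$exons$transcript_id == tid, ]
    ex <- ex[order(ex$rank), ]
    len <- ex$end - ex$start
    tx_end <- cumsum(len)
    maps[[tid]] <- data.frame(tx_start = tx_end - len, tx_end = tx_end,
                              g_start = ex$start, g_end = ex$end)
  }
  maps
}

#' Simulate barcoded full-length cDNA molecules
#'
#' Emits one molecule per (cell, feature) draw from a Poisson around the
#' design expectation, builds the read for each molecule
#' (5' primer + cell barcode + UMI + cDNA + polyA + 3' primer, a random half
#' reverse-complemented), applies per-stage truncation to gene-derived
#' molecules, adds TE-locus molecules, TE-gene chimeric molecules and
#' spike-ins, emits PCR duplicates, and records exact ground truth plus
#' spliced truth alignments (SAM-ready; chimeric molecules get a primary
#' gene segment and a supplementary TE segment; read names carry
#' `read_id|barcode|UMI`).
#'
#' 3'-partial molecules end strictly before the annotated stop codon;
#' 5'-partial molecules start strictly after the start codon; internal
#' fragments lose both. All retain at least 110 codons of open reading
#' frame so ORF typing is driven by codon content, not length censoring.
#'
#' @param reference a `toy_reference`
#' @param design an `experiment_design`
#' @return an object of class `sc_simulation`: list with `reads`
#'   (read-level table: read_id, molecule_id, sequence in sense orientation,
#'   orientation, observed/true barcode, umi), `truth` (one row per
#'   molecule), `alignments` (a [spliced_alignments] table, one or two
#'   segments per read), and the `design`
#' @export
simulate_molecules <- function(reference, design) {
  stopifnot(inherits(reference, "toy_reference"),
            inherits(design, "experiment_design"))
  set.seed(as.integer(design$seed %% 2147483647))
  lambda <- design$expression_program
  cells <- design$cells
  feats <- design$features
  tx_seqs <- transcript_sequences(reference)
  tx_maps <- build_tx_maps(reference)
  tx_info <- reference$transcripts
  rownames(tx_info) <- tx_info$transcript_id
  te <- reference$te_loci
  rownames(te) <- te$locus_id
  chrom_chr <- as.character(reference$genome)
  trunc <- design$truncation_rates
  rownames(trunc) <- trunc$stage

  mol <- list()  # rows of truth
  # ---- ordinary molecules -------------------------------------------------
  lam_cells <- lambda[, cells$stage, drop = FALSE]
  counts <- matrix(rpois(length(lam_cells), lam_cells), nrow = nrow(lambda))
  idx <- which(counts > 0, arr.ind = TRUE)
  n_mol <- counts[idx]
  mol[[1L]] <- data.frame(
    cell = cells$cell_id[rep(idx[, 2L], n_mol)],
    cell_barcode = cells$barcode[rep(idx[, 2L], n_mol)],
    stage = cells$stage[rep(idx[, 2L], n_mol)],
    source_feature = feats$feature_id[rep(idx[, 1L], n_mol)],
    kind = feats$kind[rep(idx[, 1L], n_mol)],
    gene_id = feats$gene_id[rep(idx[, 1L], n_mol)],
    chimera_partner = NA_character_, stringsAsFactors = FALSE)

  # ---- spike-ins ----------------------------------------------------------
  if (design$include_spikeins && nrow(reference$spikein_designs) > 0L) {
    sp <- reference$spikein_designs
    lam_sp <- matrix(rep(sp$copies_per_cell, nrow(cells)), ncol = nrow(cells))
    cnt <- matrix(rpois(length(lam_sp), lam_sp), nrow = nrow(sp))
    idx <- which(cnt > 0, arr.ind = TRUE)
    n_mol <- cnt[idx]
    gid <- tx_info[sp$transcript_id, "gene_id"]
    mol[[2L]] <- data.frame(
      cell = cells$cell_id[rep(idx[, 2L], n_mol)],
      cell_barcode = cells$barcode[rep(idx[, 2L], n_mol)],
      stage = cells$stage[rep(idx[, 2L], n_mol)],
      source_feature = sp$transcript_id[rep(idx[, 1L], n_mol)],
      kind = "spikein",
      gene_id = gid[rep(idx[, 1L], n_mol)],
      chimera_partner = NA_character_, stringsAsFactors = FALSE)
  }

  # ---- chimeras -----------------------------------------------------------
  if (!is.null(design$chimera_pairs) && nrow(design$chimera_pairs) > 0L) {
    cp <- design$chimera_pairs
    first_iso <- tx_info$transcript_id[!duplicated(tx_info$gene_id)]
    names(first_iso) <- tx_info$gene_id[!duplicated(tx_info$gene_id)]
    lam_ch <- matrix(rep(cp$expected, nrow(cells)), ncol = nrow(cells))
    cnt <- matrix(rpois(length(lam_ch), lam_ch), nrow = nrow(cp))
    idx <- which(cnt > 0, arr.ind = TRUE)
    n_mol <- cnt[idx]
    mol[[3L]] <- data.frame(
      cell = cells$cell_id[rep(idx[, 2L], n_mol)],
      cell_barcode = cells$barcode[rep(idx[, 2L], n_mol)],
      stage = cells$stage[rep(idx[, 2L], n_mol)],
      source_feature = unname(first_iso[cp$gene_id[rep(idx[, 1L], n_mol)]]),
      kind = "chimera",
      gene_id = cp$gene_id[rep(idx[, 1L], n_mol)],
      chimera_partner = cp$te_locus[rep(idx[, 1L], n_mol)],
      stringsAsFactors = FALSE)
  }

  truth <- do.call(rbind, mol)
  n <- nrow(truth)
  truth$molecule_id <- sprintf("mol%06d", seq_len(n))
  truth$read_id <- truth$molecule_id

  # unique UMI per (cell, feature) triple
  truth$umi <- random_dna(n, design$umi_len)
  repeat {
    key <- paste(truth$cell_barcode, truth$umi, truth$source_feature)
    dup <- duplicated(key)
    if (!any(dup)) break
    truth$umi[dup] <- random_dna(sum(dup), design$umi_len)
  }

  # ---- truncation (gene-derived molecules only) ---------------------------
  is_gene <- truth$kind == "isoform"
  p3 <- trunc[truth$stage, "p3"]; p5 <- trunc[truth$stage, "p5"]
  pint <- trunc[truth$stage, "p_internal"]
  u <- runif(n)
  truth$truncation <- "none"
  truth$truncation[is_gene & u < p3] <- "three_prime"
  truth$truncation[is_gene & u >= p3 & u < p3 + p5] <- "five_prime"
  truth$truncation[is_gene & u >= p3 + p5 & u < p3 + p5 + pint] <- "internal"

  # ---- per-molecule cDNA and truth alignment ------------------------------
  min_keep <- 330L
  cdna <- character(n)
  aln_rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- truth$kind[i]
    if (k %in% c("isoform", "spikein", "chimera")) {
      tid <- truth$source_feature[i]
      tr <- tx_info[tid, ]
      L <- nchar(tx_seqs[[tid]])
      s <- 0L; e <- L
      tt <- truth$truncation[i]
      if (tt == "three_prime") {
        e <- sample(seq(tr$cds_start + 3L + min_keep, tr$cds_end - 3L), 1L)
      } else if (tt == "five_prime") {
        s <- sample(seq(tr$cds_start + 3L, tr$cds_end - 3L - min_keep), 1L)
      } else if (tt == "internal") {
        s <- sample(seq(tr$cds_start + 3L, tr$cds_end - 3L - min_keep - 60L),
                    1L)
        e <- sample(seq(s + min_keep, tr$cds_end - 3L), 1L)
      }
      gene_cdna <- substr(tx_seqs[[tid]], s + 1L, e)
      bl <- tx_interval_to_blocks(tx_maps[[tid]], s, e, tr$strand)
      if (k == "chimera") {
        loc <- te[truth$chimera_partner[i], ]
        llen <- loc$end - loc$start
        seg_len <- min(llen, sample(150:800, 1L))
        off <- if (llen > seg_len) sample(0:(llen - seg_len), 1L) else 0L
        te_s <- loc$start + off
        te_seq <- substr(chrom_chr[[loc$chrom]], te_s + 1L, te_s + seg_len)
        cdna[i] <- paste0(te_seq, gene_cdna)
        qn <- truth$molecule_id[i]
        aln_rows[[i]] <- list(
          list(read_id = qn, chrom = tr$chrom, strand = tr$strand,
               mapq = 60L, blocks = bl, primary = TRUE, supp = FALSE),
          list(read_id = qn, chrom = loc$chrom, strand = "+", mapq = 60L,
               blocks = cbind(start = te_s, end = te_s + seg_len),
               primary = FALSE, supp = TRUE))
      } else {
        cdna[i] <- gene_cdna
        aln_rows[[i]] <- list(list(
          read_id = truth$molecule_id[i], chrom = tr$chrom,
          strand = tr$strand, mapq = 60L, blocks = bl,
          primary = TRUE, supp = FALSE))
      }
    } else { # te_locus
      loc <- te[truth$source_feature[i], ]
      llen <- loc$end - loc$start
      seg_len <- min(llen, sample(150:1200, 1L))
      off <- if (llen > seg_len) sample(0:(llen - seg_len), 1L) else 0L
      te_s <- loc$start + off
      sq <- substr(chrom_chr[[loc$chrom]], te_s + 1L, te_s + seg_len)
      strand <- loc$strand
      if (strand == "-") sq <- revcomp(sq)
      cdna[i] <- sq
      aln_rows[[i]] <- list(list(
        read_id = truth$molecule_id[i], chrom = loc$chrom, strand = strand,
        mapq = 60L, blocks = cbind(start = te_s, end = te_s + seg_len),
        primary = TRUE, supp = FALSE))
    }
  }

  # ---- PCR duplicates -----------------------------------------------------
  extra <- rpois(n, design$dup_rate)
  rep_idx <- rep(seq_len(n), 1L + extra)
  dup_rank <- sequence(1L + extra) - 1L
  read_id <- ifelse(dup_rank == 0L, truth$molecule_id[rep_idx],
                    paste0(truth$molecule_id[rep_idx], "_d", dup_rank))

  reads <- data.frame(
    read_id = read_id, molecule_id = truth$molecule_id[rep_idx],
    true_barcode = truth$cell_barcode[rep_idx],
    observed_barcode = truth$cell_barcode[rep_idx],
    umi = truth$umi[rep_idx],
    orientation = sample(c("+", "-"), length(rep_idx), replace = TRUE),
    stringsAsFactors = FALSE)
  reads$sequence <- paste0(
    design$primer_5, reads$observed_barcode, reads$umi, cdna[rep_idx],
    strrep("A", design$polya_len), design$primer_3)
  if (design$error_rate > 0) {
    reads$sequence <- add_substitutions(reads$sequence, design$error_rate)
  }
  attr(reads, "layout") <- list(primer_5 = design$primer_5,
                                primer_3 = design$primer_3,
                                bc_len = design$bc_len,
                                umi_len = design$umi_len)

  # ---- truth alignments (one entry per read, duplicates included) ---------
  aln_flat <- unlist(aln_rows[rep_idx], recursive = FALSE)
  qname_of <- function(rid, mid) {
    paste(rid, truth$cell_barcode[match(mid, truth$molecule_id)],
          truth$umi[match(mid, truth$molecule_id)], sep = "|")
  }
  # duplicate-read segments carry the duplicate read id in their name
  seg_per_read <- lengths(aln_rows[rep_idx])
  seg_read_id <- rep(read_id, seg_per_read)
  seg_mol_id <- rep(truth$molecule_id[rep_idx], seg_per_read)
  alignments <- new_alignments(
    read_id = qname_of(seg_read_id, seg_mol_id),
    chrom = vapply(aln_flat, `[[`, character(1), "chrom"),
    strand = vapply(aln_flat, `[[`, character(1), "strand"),
    mapq = vapply(aln_flat, function(a) as.integer(a$mapq), integer(1)),
    blocks = lapply(aln_flat, `[[`, "blocks"),
    is_primary = vapply(aln_flat, `[[`, logical(1), "primary"),
    is_supplementary = vapply(aln_flat, `[[`, logical(1), "supp"))

  truth <- truth[, c("molecule_id", "read_id", "cell", "cell_barcode",
                     "umi", "stage", "source_feature", "kind", "gene_id",
                     "truncation", "chimera_partner")]
  structure(list(reads = reads, truth = truth, alignments = alignments,
                 cdna = setNames(cdna, truth$molecule_id), design = design),
            class = "sc_simulation")
}

add_substitutions <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hits <- which(runif(n) < rate)
    if (length(hits) == 0L) return(s)
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    v[hits] <- vapply(v[hits],
                      function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1))
    paste0(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.sc_simulation <- function(x, ...) {
  cat("sc_simulation:", nrow(x$truth), "molecules,",
      nrow(x$reads), "reads (incl. duplicates),",
      nrow(x$alignments), "truth alignment segments\n")
  invisible(x)
}

#' Introduce single-base cell-barcode errors
#'
#' A Bernoulli(`rate`) subset of reads gets exactly one substituted position
#' in the observed cell barcode (both in the metadata column and inside the
#' read sequence); `true_barcode` keeps the original, so correction can be
#' scored against truth.
#'
#' @param reads the read table of an `sc_simulation` (or the simulation
#'   object itself, in which case it is returned with reads replaced)
#' @param rate probability in \[0,1\] that a read's barcode is corrupted
#' @param seed integer seed
#' @return same type as `reads`
#' @export
corrupt_barcodes <- function(reads, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  sim <- NULL
  if (inherits(reads, "sc_simulation")) {
    sim <- reads; reads <- sim$reads
  }
  layout <- attr(reads, "layout")
  set.seed(as.integer(seed %% 2147483647))
  hit <- which(runif(nrow(reads)) < rate)
  if (length(hit) > 0L) {
    p0 <- nchar(layout$primer_5)
    for (i in hit) {
      bc <- reads$observed_barcode[i]
      pos <- sample(nchar(bc), 1L)
      old <- substr(bc, pos, pos)
      substr(bc, pos, pos) <- sample(setdiff(DNA_BASES, old), 1L)
      reads$observed_barcode[i] <- bc
      substr(reads$sequence[i], p0 + pos, p0 + pos) <-
        substr(bc, pos, pos)
    }
  }
  attr(reads, "n_corrupted") <- length(hit)
  if (!is.null(sim)) { sim$reads <- reads; return(sim) }
  reads
}

#' Write simulator ground truth as TSV tables
#'
#' Writes `molecule_truth.tsv`, and (when present in the design)
#' `planted_stage_specific.tsv`, `planted_switches.tsv` and
#' `chimera_pairs.tsv`. All are plain TSV and round-trip with
#' [read_truth_tables()].
#'
#' @param truth molecule-truth table of an `sc_simulation`
#' @param design the `experiment_design`
#' @param directory output directory (created if needed)
#' @return character vector of written paths, invisibly
#' @export
write_truth_tables <- function(truth, design, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory)
  }
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(directory, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(paths, wr(truth, "molecule_truth.tsv"))
  if (!is.null(design$planted_stage_specific)) {
    paths <- c(paths, wr(design$planted_stage_specific,
                         "planted_stage_specific.tsv"))
  }
  if (!is.null(design$planted_switches)) {
    paths <- c(paths, wr(design$planted_switches, "planted_switches.tsv"))
  }
  if (!is.null(design$chimera_pairs)) {
    paths <- c(paths, wr(design$chimera_pairs, "chimera_pairs.tsv"))
  }
  invisible(paths)
}

#' Read back truth tables written by [write_truth_tables()]
#'
#' @param directory directory holding the TSVs
#' @return named list of data.frames (only the files present)
#' @export
read_truth_tables <- function(directory) {
  files <- c(molecule_truth = "molecule_truth.tsv",
             planted_stage_specific = "planted_stage_specific.tsv",
             planted_switches = "planted_switches.tsv",
             chimera_pairs = "chimera_pairs.tsv")
  out <- list()
  for (nm in names(files)) {
    p <- file.path(directory, files[[nm]])
    if (file.exists(p)) {
      out[[nm]] <- read.delim(p, stringsAsFactors = FALSE)
    }
  }
  out
}

#' Write simulated reads as FASTQ
#'
#' Reads flagged with orientation `-` are reverse-complemented, emulating
#' unknown molecule orientation. Qualities are constant (near-perfect
#' consensus reads).
#'
#' @param reads read table of an `sc_simulation`
#' @param path output FASTQ
#' @return `path`, invisibly
#' @export
write_reads_fastq <- function(reads, path) {
  sq <- reads$sequence
  rev <- reads$orientation == "-"
  sq[rev] <- revcomp(sq[rev])
  x <- Biostrings::DNAStringSet(sq)
  names(x) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(sq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ/FASTA file into a named character vector
#'
#' @param path FASTQ or FASTA file
#' @return named character vector of sequences
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
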