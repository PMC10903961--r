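#' Collapse spliced alignments into nonredundant isoforms
#'
#' Multi-exon reads merge into one isoform when their intron chains are
#' identical and their terminal exon ends lie within a tolerance window
#' (single-linkage within the chain group, 5' then 3'). A read whose chain
#' is a strict 3'-anchored suffix of another's is never merged - it keeps
#' its own isoform, preserving genuine 5'-shortened models. Mono-exon reads
#' merge by reciprocal overlap. Collapsed isoforms are grouped into gene
#' clusters (overlapping spans on one strand) and numbered
#' `PB.<cluster>.<n>`.
#'
#' Only primary, non-supplementary alignment segments are used.
#'
#' @param alignments a [spliced_alignments] data.frame
#' @param tol_5,tol_3 terminal tolerance (nt) at the 5' and 3' ends for
#'   chain-identical merging
#' @param mono_overlap minimum reciprocal overlap for merging mono-exon
#'   reads
#' @return an `isoform_models` data.frame: isoform_id, chrom, strand,
#'   start, end, n_exons, chain, blocks (list), support (list of read ids),
#'   n_reads
#' @export
collapse_isoforms <- function(alignments, tol_5 = 50L, tol_3 = 50L,
                              mono_overlap = 0.5) {
  a <- alignments[alignments$is_primary & !alignments$is_supplementary, ,
                  drop = FALSE]
  if (nrow(a) == 0L) {
    out <- data.frame(isoform_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), n_exons = integer(0),
                      chain = character(0), n_reads = integer(0))
    out$blocks <- list(); out$support <- list()
    class(out) <- c("isoform_models", "data.frame")
    return(out)
  }
  a$chain <- vapply(a$blocks, chain_key, character(1))
  a$n_exons <- vapply(a$blocks, nrow, integer(1))
  groups <- split(seq_len(nrow(a)),
                  paste(a$chrom, a$strand, sep = "\r"))
  iso <- list()
  for (g in groups) {
    sub <- a[g, , drop = FALSE]
    multi <- sub[sub$n_exons > 1L, , drop = FALSE]
    mono <- sub[sub$n_exons == 1L, , drop = FALSE]
    if (nrow(multi) > 0L) {
      for (ch in unique(multi$chain)) {
        mm <- multi[multi$chain == ch, , drop = FALSE]
        plus <- mm$strand[1L] == "+"
        comp <- terminal_components(mm$start, mm$end,
                                    if (plus) tol_5 else tol_3,
                                    if (plus) tol_3 else tol_5)
        for (cc in unique(comp)) {
          iso[[length(iso) + 1L]] <-
            make_isoform(mm[comp == cc, , drop = FALSE])
        }
      }
    }
    if (nrow(mono) > 0L) {
      comp <- mono_components(mono$start, mono$end, mono_overlap)
      for (cc in unique(comp)) {
        iso[[length(iso) + 1L]] <-
          make_isoform(mono[comp == cc, , drop = FALSE])
      }
    }
  }
  out <- do.call(rbind, lapply(iso, `[`,
                               c("chrom", "strand", "start", "end",
                                 "n_exons", "chain", "n_reads")))
  out$blocks <- lapply(iso, function(d) d$blocks[[1L]])
  out$support <- lapply(iso, function(d) d$support[[1L]])
  out <- assign_pb_ids(out)
  class(out) <- c("isoform_models", "data.frame")
  out
}

# transitive closure of pairwise terminal-end compatibility: reads i, j are
# directly mergeable when |start_i - start_j| <= tol_left and
# |end_i - end_j| <= tol_right; components via union-find over a
# start-sorted sweep (pairs farther than tol_left apart need no check)
terminal_components <- function(start, end, tol_left, tol_right) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  o <- order(start, end)
  for (ii in seq_len(n)) {
    i <- o[ii]
    jj <- ii + 1L
    while (jj <= n && start[o[jj]] - start[i] <= tol_left) {
      j <- o[jj]
      if (abs(end[i] - end[j]) <= tol_right) parent[find(j)] <- find(i)
      jj <- jj + 1L
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# connected components of mono-exon intervals under reciprocal overlap;
# sweep over start-sorted intervals so only overlapping pairs are compared
mono_components <- function(start, end, frac) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  o <- order(start, end)
  for (ii in seq_len(n)) {
    i <- o[ii]
    jj <- ii + 1L
    while (jj <= n && start[o[jj]] < end[i]) {
      j <- o[jj]
      ov <- interval_overlap(start[i], end[i], start[j], end[j])
      if (ov >= frac * (end[i] - start[i]) &&
            ov >= frac * (end[j] - start[j])) {
        parent[find(j)] <- find(i)
      }
      jj <- jj + 1L
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# The representative model of a merged group is its longest member read
# (ties: leftmost, then read id). Using an actual member - rather than the
# union span - makes collapse idempotent: representatives of two distinct
# groups are never directly mergeable, or the groups would have merged.
make_isoform <- function(members) {
  o <- order(-(members$end - members$start), members$start,
             members$read_id)
  rep_i <- o[1L]
  df <- data.frame(chrom = members$chrom[1L], strand = members$strand[1L],
                   start = members$start[rep_i], end = members$end[rep_i],
                   n_exons = members$n_exons[1L],
                   chain = members$chain[1L], n_reads = nrow(members),
                   stringsAsFactors = FALSE)
  df$blocks <- list(members$blocks[[rep_i]])
  df$support <- list(members$read_id)
  df
}

# PB-style ids: gene clusters = overlapping spans on one strand,
# numbered along the genome; isoforms numbered within cluster.
assign_pb_ids <- function(iso) {
  iso <- iso[order(iso$chrom, iso$strand, iso$start, iso$end, iso$chain), ,
             drop = FALSE]
  cluster <- integer(nrow(iso))
  cur <- 0L; cur_chrom <- ""; cur_strand <- ""; cur_end <- -1
  for (i in seq_len(nrow(iso))) {
    if (iso$chrom[i] != cur_chrom || iso$strand[i] != cur_strand ||
          iso$start[i] >= cur_end) {
      cur <- cur + 1L
      cur_chrom <- iso$chrom[i]; cur_strand <- iso$strand[i]
      cur_end <- iso$end[i]
    } else {
      cur_end <- max(cur_end, iso$end[i])
    }
    cluster[i] <- cur
  }
  iso$gene_cluster <- cluster
  n_in <- stats::ave(seq_len(nrow(iso)), cluster, FUN = seq_along)
  iso$isoform_id <- sprintf("PB.%d.%d", cluster, n_in)
  rownames(iso) <- NULL
  iso[, c("isoform_id", "gene_cluster", "chrom", "strand", "start", "end",
          "n_exons", "chain", "n_reads", "blocks", "support")]
}

#' Classify isoforms against reference gene models
#'
#' Structural classes follow the standard long-read taxonomy:
#' `FSM` (full splice match: intron chain equals a reference transcript's),
#' `ISM` (incomplete splice match: chain is a consecutive sub-chain of a
#' reference chain), `NIC` (novel in catalog: all splice sites annotated
#' but the chain is new), `NNC` (novel not in catalog: at least one novel
#' splice site), and `other` (antisense, intergenic, or unmatched mono-exon
#' models). The assigned gene is the same-strand reference gene with the
#' largest exonic overlap.
#'
#' @param isoforms an `isoform_models` data.frame (or any table with chrom,
#'   strand, start, end, chain, blocks)
#' @param reference a `toy_reference`, or a list with `genes`,
#'   `transcripts`, `exons` tables in the same layout
#' @return `isoforms` with `structural_class` and `assigned_gene` columns
#' @export
classify_structural <- function(isoforms, reference) {
  ref <- reference_chain_index(reference)
  n <- nrow(isoforms)
  cls <- character(n); gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    r <- classify_one_isoform(
      isoforms$chrom[i], isoforms$strand[i], isoforms$start[i],
      isoforms$end[i], isoforms$blocks[[i]], ref)
    cls[i] <- r$class; gene[i] <- r$gene
  }
  isoforms$structural_class <- cls
  isoforms$assigned_gene <- gene
  isoforms
}

# Precompute reference chains, splice sites, exon tables per (chrom, strand).
reference_chain_index <- function(reference) {
  tx <- reference$transcripts
  ex <- reference$exons
  genes <- reference$genes
  chains <- list(); sites <- list()
  for (tid in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tid, ]
    e <- e[order(e$start), ]
    bl <- cbind(start = e$start, end = e$end)
    key <- paste(e$chrom[1L], e$strand[1L], sep = "\r")
    jn <- chain_junctions(bl)
    chains[[tid]] <- list(key = key, chain = chain_key(bl), junctions = jn,
                          blocks = bl,
                          gene = tx$gene_id[match(tid, tx$transcript_id)])
    if (nrow(jn) > 0L) {
      sites[[key]] <- c(sites[[key]], jn[, 1L], jn[, 2L])
    }
  }
  list(chains = chains, sites = lapply(sites, unique), genes = genes,
       exons = ex, transcripts = tx)
}

classify_one_isoform <- function(chrom, strand, start, end, blocks, ref) {
  key <- paste(chrom, strand, sep = "\r")
  g <- ref$genes
  same <- g$chrom == chrom & g$strand == strand &
    g$start < end & g$end > start
  gene <- NA_character_
  if (any(same)) {
    ov <- interval_overlap(g$start[same], g$end[same], start, end)
    gene <- g$gene_id[same][which.max(ov)]
  }
  jn <- chain_junctions(blocks)
  if (nrow(jn) == 0L) {
    # mono-exon: match against mono-exon reference transcripts
    for (tid in names(ref$chains)) {
      ch <- ref$chains[[tid]]
      if (ch$key == key && nrow(ch$junctions) == 0L) {
        ov <- interval_overlap(ch$blocks[1L, 1L], ch$blocks[1L, 2L],
                               start, end)
        if (ov >= 0.5 * (end - start) &&
              ov >= 0.5 * (ch$blocks[1L, 2L] - ch$blocks[1L, 1L])) {
          return(list(class = "FSM", gene = ch$gene))
        }
      }
    }
    return(list(class = "other", gene = gene))
  }
  if (is.na(gene)) return(list(class = "other", gene = NA_character_))
  chain <- chain_key(blocks)
  ism <- FALSE
  for (tid in names(ref$chains)) {
    ch <- ref$chains[[tid]]
    if (ch$key != key) next
    if (identical(ch$chain, chain)) {
      return(list(class = "FSM", gene = ch$gene))
    }
    if (!ism && is_consecutive_subchain(jn, ch$junctions)) ism <- TRUE
  }
  if (ism) return(list(class = "ISM", gene = gene))
  known <- ref$sites[[key]] %||% integer(0)
  if (all(jn %in% known)) return(list(class = "NIC", gene = gene))
  list(class = "NNC", gene = gene)
}

# TRUE if junction set a (k x 2) appears as a consecutive run inside b.
is_consecutive_subchain <- function(a, b) {
  ka <- nrow(a); kb <- nrow(b)
  if (ka == 0L || ka > kb) return(FALSE)
  for (off in 0:(kb - ka)) {
    if (all(a == b[off + seq_len(ka), , drop = FALSE])) return(TRUE)
  }
  FALSE
}

#' Flag CAGE support of isoform 5' ends
#'
#' An isoform is CAGE-supported when its 5'-terminal genomic position lies
#' within `max_dist` nt of a same-strand CAGE peak (distance 0 inside or at
#' the edge of the peak).
#'
#' @param isoforms an `isoform_models` data.frame
#' @param peaks data.frame(chrom, start, end, strand), 0-based half-open
#' @param max_dist maximum distance in nt (default 200)
#' @return logical vector, one flag per isoform
#' @export
flag_cage_support <- function(isoforms, peaks, max_dist = 200L) {
  vapply(seq_len(nrow(isoforms)), function(i) {
    p5 <- if (isoforms$strand[i] == "+") isoforms$start[i]
          else isoforms$end[i] - 1L
    same <- peaks$chrom == isoforms$chrom[i] &
      peaks$strand == isoforms$strand[i]
    if (!any(same)) return(FALSE)
    d <- pmax(0L, peaks$start[same] - p5, p5 - (peaks$end[same] - 1L))
    min(d) <= max_dist
  }, logical(1))
}

#' Extract the spliced sequence of alignments or isoform models
#'
#' Concatenates the genomic sequence of the exon blocks, reverse
#' complemented for minus-strand records, yielding the transcript-oriented
#' sequence.
#'
#' @param genome a DNAStringSet (e.g. `toy_reference$genome`)
#' @param records a [spliced_alignments] or `isoform_models` data.frame
#' @return character vector of sequences
#' @export
spliced_sequences <- function(genome, records) {
  chrom_chr <- as.character(genome)
  vapply(seq_len(nrow(records)), function(i) {
    bl <- records$blocks[[i]]
    s <- paste0(substring(chrom_chr[[records$chrom[i]]],
                          bl[, 1L] + 1L, bl[, 2L]), collapse = "")
    if (records$strand[i] == "-") s <- revcomp(s)
    s
  }, character(1))
}

#' Assign alignments to reference genes by exonic overlap
#'
#' The internal gene assigner: each primary alignment is assigned to the
#' same-strand reference gene with the largest exonic overlap (at least
#' `min_overlap` nt); spike-in genes are included. Reads with supplementary
#' segments should be routed to chimera detection instead.
#'
#' @param alignments a [spliced_alignments] data.frame
#' @param reference a `toy_reference` (or list with genes/transcripts/exons)
#' @param min_overlap minimum exonic overlap in nt (default 50)
#' @return character vector of gene ids (NA where unassigned), parallel to
#'   `alignments`
#' @export
assign_to_genes <- function(alignments, reference, min_overlap = 50L) {
  ex <- reference$exons
  gene_of_tx <- setNames(reference$transcripts$gene_id,
                         reference$transcripts$transcript_id)
  ex_gene <- gene_of_tx[ex$transcript_id]
  exg <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end),
    strand = ex$strand, gene = ex_gene)
  exg <- unique(exg)
  n <- nrow(alignments)
  nb <- vapply(alignments$blocks, nrow, integer(1))
  bl <- do.call(rbind, alignments$blocks)
  qgr <- GenomicRanges::GRanges(
    rep(alignments$chrom, nb),
    IRanges::IRanges(bl[, 1L] + 1L, bl[, 2L]),
    strand = rep(alignments$strand, nb))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(qgr, exg))
  out <- rep(NA_character_, n)
  if (length(hits) == 0L) return(out)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(qgr)[qh],
                                           IRanges::ranges(exg)[sh]))
  df <- data.frame(read = rep(seq_len(n), nb)[qh],
                   gene = exg$gene[sh], ov = ov)
  agg <- stats::aggregate(ov ~ read + gene, data = df, FUN = sum)
  agg <- agg[agg$ov >= min_overlap, , drop = FALSE]
  agg <- agg[order(agg$read, -agg$ov, agg$gene), , drop = FALSE]
  best <- agg[!duplicated(agg$read), ]
  out[best$read] <- best$gene
  out
}

#' Assign alignments to reference transcripts by intron chain
#'
#' Multi-exon alignments are assigned to the reference transcript whose
#' intron chain they match exactly (full splice match); unmatched reads
#' fall back to the same-strand transcript with the largest exonic
#' overlap. Used for spike-in isoform identification.
#'
#' @param alignments a [spliced_alignments] data.frame
#' @param reference a `toy_reference`
#' @return character vector of transcript ids (NA where unassigned)
#' @export
assign_to_transcripts <- function(alignments, reference) {
  ref <- reference_chain_index(reference)
  keys <- vapply(names(ref$chains), function(t) ref$chains[[t]]$key,
                 character(1))
  chains <- vapply(names(ref$chains), function(t) ref$chains[[t]]$chain,
                   character(1))
  n <- nrow(alignments)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    key <- paste(alignments$chrom[i], alignments$strand[i], sep = "\r")
    ch <- chain_key(alignments$blocks[[i]])
    hit <- which(keys == key & chains == ch & ch != "")
    if (length(hit) >= 1L) {
      out[i] <- names(ref$chains)[hit[1L]]
      next
    }
    # fallback: largest exonic overlap
    best_ov <- 0L
    for (tid in names(ref$chains)[keys == key]) {
      bl <- ref$chains[[tid]]$blocks
      ov <- 0L
      for (j in seq_len(nrow(alignments$blocks[[i]]))) {
        ov <- ov + sum(interval_overlap(
          alignments$blocks[[i]][j, 1L], alignments$blocks[[i]][j, 2L],
          bl[, 1L], bl[, 2L]))
      }
      if (ov > best_ov) { best_ov <- ov; out[i] <- tid }
    }
  }
  out
}
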