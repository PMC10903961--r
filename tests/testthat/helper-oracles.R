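# Independent brute-force oracles used across the suite. These deliberately
# re-derive the rules from their definitions with naive scans, so that the
# package implementations are checked against a second, simpler code path.

# -- longest-ORF oracle: exhaustive enumeration over 3 frames ---------------
orf_oracle <- function(s) {
  L <- nchar(s)
  best <- NULL
  consider <- function(cd) {
    if (is.null(best)) { best <<- cd; return(invisible()) }
    ka <- c(cd$length_aa, cd$has_start_codon, cd$has_stop_codon,
            -cd$orf_start, -cd$frame)
    kb <- c(best$length_aa, best$has_start_codon, best$has_stop_codon,
            -best$orf_start, -best$frame)
    nz <- which(ka != kb)
    if (length(nz) > 0L && ka[nz[1L]] > kb[nz[1L]]) best <<- cd
  }
  for (f in 0:2) {
    nc <- (L - f) %/% 3
    if (nc < 1) next
    cod <- substring(s, f + 3 * (seq_len(nc) - 1) + 1, f + 3 * seq_len(nc))
    is_stop <- cod %in% c("TAA", "TAG", "TGA")
    is_atg <- cod == "ATG"
    stops <- which(is_stop)
    seg_start <- 1L
    for (st in stops) {
      seg_atgs <- which(is_atg & seq_len(nc) >= seg_start &
                          seq_len(nc) < st)
      if (length(seg_atgs) > 0) {
        consider(data.frame(orf_start = f + 3 * (seg_atgs[1] - 1),
                            orf_end = f + 3 * st, frame = f,
                            has_start_codon = TRUE, has_stop_codon = TRUE,
                            length_aa = st - seg_atgs[1]))
      } else if (seg_start == 1L && st > 1L) {
        consider(data.frame(orf_start = f, orf_end = f + 3 * st, frame = f,
                            has_start_codon = FALSE, has_stop_codon = TRUE,
                            length_aa = st - 1))
      }
      seg_start <- st + 1L
    }
    tail_atgs <- which(is_atg & seq_len(nc) >= seg_start)
    if (length(tail_atgs) > 0) {
      consider(data.frame(orf_start = f + 3 * (tail_atgs[1] - 1),
                          orf_end = f + 3 * nc, frame = f,
                          has_start_codon = TRUE, has_stop_codon = FALSE,
                          length_aa = nc - tail_atgs[1] + 1))
    } else if (length(stops) == 0L) {
      consider(data.frame(orf_start = f, orf_end = f + 3 * nc, frame = f,
                          has_start_codon = FALSE, has_stop_codon = FALSE,
                          length_aa = nc))
    }
  }
  best
}

# -- TE-assignment oracle: direct linear scan of the rules ------------------
te_oracle <- function(alignments, loci, min_mapq = 30L) {
  n <- nrow(alignments)
  out <- data.frame(read_id = alignments$read_id,
                    locus_id = NA_character_, overlap_length = 0L,
                    rejection_reason = "none", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (!(alignments$is_primary[i] && !alignments$is_secondary[i] &&
            !alignments$is_supplementary[i] &&
            alignments$mapq[i] >= min_mapq)) {
      out$rejection_reason[i] <- "not_unique"; next
    }
    b <- alignments$blocks[[i]]
    same <- loci$chrom == alignments$chrom[i]
    ovs <- numeric(nrow(loci))
    for (k in seq_len(nrow(b))) {
      ovs <- ovs + ifelse(same, pmax(0, pmin(b[k, 2], loci$end) -
                                       pmax(b[k, 1], loci$start)), 0)
    }
    if (all(ovs == 0)) { out$rejection_reason[i] <- "no_overlap"; next }
    p1 <- alignments$start[i]; p2 <- alignments$end[i] - 1
    cand <- which(ovs > 0 & same &
                    ((p1 >= loci$start & p1 < loci$end) |
                       (p2 >= loci$start & p2 < loci$end)))
    if (length(cand) == 0) {
      out$rejection_reason[i] <- "endpoints_outside"; next
    }
    j <- cand[order(-ovs[cand], loci$start[cand], loci$locus_id[cand])][1]
    out$locus_id[i] <- loci$locus_id[j]
    out$overlap_length[i] <- ovs[j]
  }
  out
}

# -- collapse oracle: quadratic all-pairs merge test ------------------------
# mergeable iff same chrom/strand and (multi-exon: identical chain with both
# terminal ends within tolerance) or (mono-exon: reciprocal overlap >= frac);
# transitive closure via repeated sweeps.
collapse_oracle <- function(alignments, tol = 50L, frac = 0.5) {
  a <- alignments[alignments$is_primary & !alignments$is_supplementary, ]
  n <- nrow(a)
  chain <- vapply(a$blocks, scisote:::chain_key, character(1))
  comp <- seq_len(n)
  mergeable <- function(i, j) {
    if (a$chrom[i] != a$chrom[j] || a$strand[i] != a$strand[j]) return(FALSE)
    mi <- nrow(a$blocks[[i]]) > 1; mj <- nrow(a$blocks[[j]]) > 1
    if (mi != mj) return(FALSE)
    if (mi) {
      chain[i] == chain[j] && abs(a$start[i] - a$start[j]) <= tol &&
        abs(a$end[i] - a$end[j]) <= tol
    } else {
      ov <- max(0, min(a$end[i], a$end[j]) - max(a$start[i], a$start[j]))
      ov >= frac * (a$end[i] - a$start[i]) &&
        ov >= frac * (a$end[j] - a$start[j])
    }
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && mergeable(i, j)) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# -- structural-class oracle: exhaustive reference-chain comparison ---------
structural_oracle <- function(iso_row, reference) {
  blocks <- iso_row$blocks[[1]]
  jn <- scisote:::chain_junctions(blocks)
  g <- reference$genes
  same <- g$chrom == iso_row$chrom & g$strand == iso_row$strand &
    g$start < iso_row$end & g$end > iso_row$start
  if (nrow(jn) == 0) return("other_or_fsm_mono")
  if (!any(same)) return("other")
  sites <- c(); found_fsm <- FALSE; found_ism <- FALSE
  for (tid in unique(reference$exons$transcript_id)) {
    e <- reference$exons[reference$exons$transcript_id == tid, ]
    if (e$chrom[1] != iso_row$chrom || e$strand[1] != iso_row$strand) next
    e <- e[order(e$start), ]
    bl <- cbind(e$start, e$end)
    rj <- scisote:::chain_junctions(bl)
    if (nrow(rj) > 0) sites <- c(sites, rj[, 1], rj[, 2])
    if (nrow(rj) == nrow(jn) && all(rj == jn)) found_fsm <- TRUE
    if (nrow(rj) > nrow(jn)) {
      for (off in 0:(nrow(rj) - nrow(jn))) {
        if (all(jn == rj[off + seq_len(nrow(jn)), , drop = FALSE]))
          found_ism <- TRUE
      }
    }
  }
  if (found_fsm) return("FSM")
  if (found_ism) return("ISM")
  if (all(jn %in% sites)) return("NIC")
  "NNC"
}

# -- two-sided Fisher p for a 2x2 table via hypergeometric enumeration ------
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# shared tiny fixtures ------------------------------------------------------
tiny_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_toy_reference(seed = 101, n_genes = 6, n_te_loci = 12,
                                    n_spikein_genes = 3)
    }
    cache
  }
})

tiny_simulation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- tiny_reference()
      cp <- data.frame(te_locus = ref$te_loci$locus_id[1:2],
                       gene_id = ref$genes$gene_id[1:2], expected = 0.3)
      des <- experiment_design(ref, stages = c("oocyte", "zygote", "E2C",
                                               "L2C"),
                               cells_per_stage = 3L, seed = 202,
                               include_spikeins = TRUE, chimera_pairs = cp)
      cache <<- simulate_molecules(ref, des)
    }
    cache
  }
})

random_te_instance <- function(seed, n_loci = 60, n_reads = 300,
                               span = 400000) {
  set.seed(seed)
  loci <- data.frame(chrom = sample(c("chr1", "chr2"), n_loci,
                                    replace = TRUE),
                     start = sample(0:span, n_loci), strand = "+",
                     rep_name = "Lx7", rep_family = "L1",
                     rep_class = "LINE")
  loci$end <- loci$start + sample(100:2000, n_loci, replace = TRUE)
  loci$locus_id <- sprintf("L%04d", seq_len(n_loci))
  blocks <- lapply(seq_len(n_reads), function(i) {
    ne <- sample(1:3, 1); s <- sample(0:span, 1)
    st <- s + cumsum(c(0, sample(200:2000, ne - 1, replace = TRUE)))
    w <- sample(100:800, ne, replace = TRUE)
    cbind(start = st, end = st + w)
  })
  al <- scisote:::new_alignments(
    sprintf("r%05d", seq_len(n_reads)),
    sample(c("chr1", "chr2"), n_reads, replace = TRUE), "+",
    sample(c(0L, 60L), n_reads, replace = TRUE, prob = c(0.1, 0.9)),
    blocks)
  list(loci = loci, alignments = al)
}
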