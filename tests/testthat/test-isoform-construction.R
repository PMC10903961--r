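mk_al <- function(ids, chrom, strand, mapq, blocks, ...) {
  scisote:::new_alignments(ids, chrom, strand, mapq, blocks, ...)
}

test_that("identical chains with jittered 3' ends merge; suffixes do not", {
  b1 <- cbind(start = c(100L, 300L, 500L), end = c(200L, 400L, 620L))
  b2 <- b1; b2[3, 2] <- 600L  # 3' end differs by 20 nt
  al <- mk_al(c("A", "B"), "chr1", "+", 60L, list(b1, b2))
  iso <- collapse_isoforms(al)
  expect_equal(nrow(iso), 1L)
  expect_equal(iso$n_reads, 2L)
  # 5'-shorter strict suffix chain keeps its own isoform
  b3 <- cbind(start = c(320L, 500L), end = c(400L, 620L))
  al2 <- mk_al(c("A", "B"), "chr1", "+", 60L, list(b1, b3))
  iso2 <- collapse_isoforms(al2)
  expect_equal(nrow(iso2), 2L)
})

test_that("collapse equals the quadratic all-pairs oracle on random reads", {
  ref <- tiny_reference()
  for (seed in 1:5) {
    set.seed(seed)
    # random reads resampled from annotated models plus mono-exon reads
    tx <- sample(ref$transcripts$transcript_id, 60, replace = TRUE)
    blocks <- lapply(tx, function(t) {
      bl <- transcript_blocks(ref, t)
      jit <- sample(-60:60, 2)
      bl[1, 1] <- bl[1, 1] + jit[1]
      bl[nrow(bl), 2] <- bl[nrow(bl), 2] + jit[2]
      bl
    })
    ch <- sample(unique(ref$transcripts$chrom), 1)
    mono <- lapply(1:40, function(i) {
      s <- sample(0:150000, 1)
      cbind(start = s, end = s + sample(150:800, 1))
    })
    info <- ref$transcripts[match(tx, ref$transcripts$transcript_id), ]
    al <- mk_al(sprintf("r%03d", 1:100),
                c(info$chrom, rep(ch, 40)),
                c(info$strand, rep("+", 40)), 60L, c(blocks, mono))
    iso <- collapse_isoforms(al)
    comp <- collapse_oracle(al)
    expect_equal(nrow(iso), length(unique(comp)))
    # identical grouping of reads
    got <- lapply(iso$support, sort)
    want <- lapply(split(al$read_id, comp), sort)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
    # read conservation and idempotence
    expect_equal(sum(lengths(iso$support)), 100L)
    iso2 <- collapse_isoforms(mk_al(iso$isoform_id, iso$chrom, iso$strand,
                                    60L, iso$blocks))
    expect_equal(nrow(iso2), nrow(iso))
  }
})

test_that("structural classes match constructed and oracle expectations", {
  ref <- tiny_reference()
  multi <- ref$transcripts$transcript_id[
    vapply(ref$transcripts$transcript_id,
           function(t) nrow(transcript_blocks(ref, t)), 0L) >= 4]
  tid <- multi[1]
  info <- ref$transcripts[ref$transcripts$transcript_id == tid, ]
  bl <- transcript_blocks(ref, tid)
  al <- mk_al("fsm", info$chrom, info$strand, 60L, list(bl))
  iso <- classify_structural(collapse_isoforms(al), ref)
  expect_equal(iso$structural_class, "FSM")
  expect_equal(iso$assigned_gene, info$gene_id)
  # middle junctions of the chain -> ISM
  mid <- bl[2:(nrow(bl) - 1), , drop = FALSE]
  iso2 <- classify_structural(
    collapse_isoforms(mk_al("ism", info$chrom, info$strand, 60L,
                            list(mid))), ref)
  expect_equal(iso2$structural_class, "ISM")
  # known splice sites in a novel combination -> NIC: skip an internal
  # exon of a gene annotated with a single isoform
  n_iso_per_gene <- table(ref$transcripts$gene_id)
  singles <- names(n_iso_per_gene)[n_iso_per_gene == 1]
  single_tx <- ref$transcripts$transcript_id[
    ref$transcripts$gene_id %in% singles]
  single_tx <- single_tx[vapply(single_tx, function(t)
    nrow(transcript_blocks(ref, t)), 0L) >= 3]
  if (length(single_tx) > 0) {
    sbl <- transcript_blocks(ref, single_tx[1])
    sinfo <- ref$transcripts[
      ref$transcripts$transcript_id == single_tx[1], ]
    nic <- sbl[-2, , drop = FALSE]
    iso3 <- classify_structural(
      collapse_isoforms(mk_al("nic", sinfo$chrom, sinfo$strand, 60L,
                              list(nic))), ref)
    expect_equal(iso3$structural_class, "NIC")
  }
  # novel splice site -> NNC
  nnc <- bl; nnc[1, 2] <- nnc[1, 2] - 7L
  iso4 <- classify_structural(
    collapse_isoforms(mk_al("nnc", info$chrom, info$strand, 60L,
                            list(nnc))), ref)
  expect_equal(iso4$structural_class, "NNC")
  # antisense -> other
  iso5 <- classify_structural(
    collapse_isoforms(mk_al("anti", info$chrom,
                            ifelse(info$strand == "+", "-", "+"), 60L,
                            list(bl))), ref)
  expect_equal(iso5$structural_class, "other")
})

test_that("random isoforms agree with the exhaustive structural oracle", {
  ref <- tiny_reference()
  sim <- tiny_simulation()
  iso <- classify_structural(collapse_isoforms(sim$alignments), ref)
  for (i in seq_len(nrow(iso))) {
    want <- structural_oracle(iso[i, ], ref)
    if (want == "other_or_fsm_mono") {
      expect_true(iso$structural_class[i] %in% c("other", "FSM"))
    } else {
      expect_equal(iso$structural_class[i], want)
    }
  }
  # structural classes partition the isoform set
  expect_true(all(iso$structural_class %in%
                    c("FSM", "ISM", "NIC", "NNC", "other")))
})

test_that("CAGE support obeys the 200 bp window", {
  peaks <- data.frame(chrom = "chr1", start = 1000L, end = 1040L,
                      strand = "+")
  mk_iso <- function(p5) {
    al <- mk_al("x", "chr1", "+", 60L,
                list(cbind(start = p5, end = p5 + 500L)))
    collapse_isoforms(al)
  }
  expect_true(flag_cage_support(mk_iso(1040L), peaks))   # edge, distance 1
  expect_true(flag_cage_support(mk_iso(1000L), peaks))   # at start edge
  expect_true(flag_cage_support(mk_iso(1239L), peaks))   # 200 away
  expect_false(flag_cage_support(mk_iso(1241L), peaks))  # 201 -> outside
  # strandedness
  peaks_minus <- transform(peaks, strand = "-")
  expect_false(flag_cage_support(mk_iso(1000L), peaks_minus))
  # random isoforms vs linear-scan oracle
  set.seed(4)
  peaks2 <- data.frame(chrom = "chr1",
                       start = sample(0:100000, 30), strand = "+")
  peaks2$end <- peaks2$start + 40L
  for (k in 1:50) {
    p5 <- sample(0:100000, 1)
    d <- pmax(0L, peaks2$start - p5, p5 - (peaks2$end - 1L))
    expect_equal(unname(flag_cage_support(mk_iso(p5), peaks2)),
                 min(d) <= 200)
  }
})

test_that("longest-ORF prediction equals exhaustive enumeration", {
  set.seed(55)
  for (i in 1:300) {
    s <- scisote:::random_dna(1, sample(40:400, 1))
    got <- predict_orf(s, min_length_aa = 1)
    want <- orf_oracle(s)
    if (is.null(want)) {
      expect_true(got$below_threshold)
    } else {
      expect_equal(got$orf_start, want$orf_start)
      expect_equal(got$orf_end, want$orf_end)
      expect_equal(got$length_aa, want$length_aa)
      expect_equal(got$has_start_codon, want$has_start_codon)
      expect_equal(got$has_stop_codon, want$has_stop_codon)
    }
  }
  expect_error(predict_orf("ACGTN"), "non-DNA")
})

test_that("constructed ORFs classify to their planted type", {
  p <- predict_orf(paste0("CCCCC", "ATGAAATGA", "CC"), min_length_aa = 2)
  expect_true(p$has_start_codon && p$has_stop_codon)
  expect_equal(classify_orf_type(p), "complete")
  # ATG-initiated ORF running off the 3' end (stops in the other frames)
  s <- paste0("TGACTAACTAGC", "ATG", strrep("GAACTAACTAGCGAA", 6))
  p2 <- predict_orf(s, min_length_aa = 2)
  expect_true(p2$has_start_codon)
  expect_false(p2$has_stop_codon)
  expect_equal(classify_orf_type(p2), "three_prime_partial")
  # below threshold -> others
  expect_equal(classify_orf_type(predict_orf("ATGAAATGA",
                                             min_length_aa = 50)),
               "others")
  expect_equal(classify_orf_type(
    data.frame(below_threshold = FALSE, has_start_codon = FALSE,
               has_stop_codon = FALSE)), "internal")
})

test_that("simulated truncations recover their ORF types", {
  sim <- tiny_simulation()
  g <- sim$truth$kind == "isoform"
  types <- vapply(sim$cdna[sim$truth$molecule_id[g]],
                  function(s) classify_orf_type(predict_orf(s)),
                  character(1))
  map <- c(none = "complete", three_prime = "three_prime_partial",
           five_prime = "five_prime_partial", internal = "internal")
  agreement <- mean(types == map[sim$truth$truncation[g]])
  expect_gte(agreement, 0.99)
})
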