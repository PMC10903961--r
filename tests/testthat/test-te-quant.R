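test_that("TE index queries equal a linear scan", {
  inst <- random_te_instance(21, n_loci = 80, n_reads = 0)
  idx <- build_te_index(inst$loci)
  # inside one locus
  l1 <- inst$loci[1, ]
  got <- query_te_index(idx, l1$chrom, l1$start + 1L, l1$start + 2L)
  expect_true(l1$locus_id %in% got$locus_id)
  set.seed(77)
  for (k in 1:500) {
    ch <- sample(c("chr1", "chr2"), 1)
    s <- sample(0:400000, 1); e <- s + sample(1:5000, 1)
    got <- sort(query_te_index(idx, ch, s, e)$locus_id)
    want <- sort(inst$loci$locus_id[
      inst$loci$chrom == ch & inst$loci$start < e & inst$loci$end > s])
    expect_equal(got, want)
  }
  expect_error(build_te_index(inst$loci[c(1, 1), ]), "duplicate")
})

test_that("single-read assignment follows the endpoint and overlap rules", {
  loci <- data.frame(
    locus_id = c("A", "B"), chrom = "chr1",
    start = c(1000L, 2000L), end = c(1400L, 3000L), strand = "+",
    rep_name = "MT2_mm", rep_family = "ERVL", rep_class = "LTR")
  idx <- build_te_index(loci)
  # read fully inside A: overlap = aligned length
  al <- scisote:::new_alignments("r1", "chr1", "+", 60L,
                                 list(cbind(start = 1100L, end = 1300L)))
  res <- assign_read_to_te(al, idx)
  expect_equal(res$locus_id, "A")
  expect_equal(res$overlap_length, 200L)
  # read starts inside A (overlap 120) but only spans B internally
  # (overlap 200, no endpoint inside B after extending past it)
  al2 <- scisote:::new_alignments(
    "r2", "chr1", "+", 60L,
    list(cbind(start = c(1280L, 2400L), end = c(1400L, 2600L))))
  # endpoints: 1280 (in A), 2599 (in B) - craft so end is outside B
  al3 <- scisote:::new_alignments(
    "r3", "chr1", "+", 60L,
    list(cbind(start = c(1280L, 2400L, 3500L),
               end = c(1400L, 2600L, 3600L))))
  res3 <- assign_read_to_te(al3, idx)
  expect_equal(res3$locus_id, "A")  # B has larger overlap but no endpoint
  expect_equal(res3$overlap_length, 120L)
  # low quality -> not unique
  al4 <- scisote:::new_alignments("r4", "chr1", "+", 10L,
                                  list(cbind(start = 1100L, end = 1300L)))
  expect_equal(assign_read_to_te(al4, idx)$rejection_reason, "not_unique")
})

test_that("assignment equals the naive rule-by-rule oracle", {
  inst <- random_te_instance(31, n_loci = 60, n_reads = 400)
  idx <- build_te_index(inst$loci)
  got <- assign_reads_to_te(inst$alignments, idx)
  want <- te_oracle(inst$alignments, inst$loci)
  expect_identical(got$locus_id, want$locus_id)
  expect_identical(got$rejection_reason, want$rejection_reason)
  expect_equal(got$overlap_length[!is.na(got$locus_id)],
               want$overlap_length[!is.na(want$locus_id)])
  # monotonicity: dropping the endpoint rule can only add assignments
  no_endpoint <- sum(want$rejection_reason %in%
                       c("none", "endpoints_outside"))
  expect_gte(no_endpoint, sum(want$rejection_reason == "none"))
})

test_that("TE matrix conserves molecules and rolls up by hierarchy", {
  sim <- tiny_simulation()
  ref <- tiny_reference()
  out <- run_toy_pipeline(sim, ref)
  m <- SummarizedExperiment::assay(out$te$matrix, "counts")
  tt <- sim$truth[sim$truth$kind == "te_locus", ]
  expect_equal(sum(m), nrow(tt))
  # each unique read contributes to at most one locus
  expect_true(all(vapply(out$te$rollups, sum, 0) == sum(m)))
  # rollup = sum of member locus rows
  rd <- SummarizedExperiment::rowData(out$te$matrix)
  fam <- out$te$rollups$rep_family
  for (f in rownames(fam)) {
    member <- rownames(m)[rd$rep_family == f]
    expect_equal(unname(fam[f, ]),
                 unname(Matrix::colSums(m[member, , drop = FALSE])))
  }
  # per-cell expressed loci match the matrix
  expect_equal(out$te$per_cell_loci$n_loci_expressed,
               unname(Matrix::colSums(m > 0)))
  # per-(cell, locus) counts equal the design truth exactly
  tr <- stats::aggregate(list(n = tt$umi),
                         by = list(bc = tt$cell_barcode,
                                   loc = tt$source_feature), FUN = length)
  expect_true(all(mapply(function(b, l, n) m[l, b] == n,
                         tr$bc, tr$loc, tr$n)))
})

test_that("per-locus molecule totals track the design expectation", {
  ref <- tiny_reference()
  des <- experiment_design(ref, stages = c("A", "B"), cells_per_stage = 10,
                           seed = 91)
  sim <- simulate_molecules(ref, des)
  tt <- sim$truth[sim$truth$kind == "te_locus", ]
  lam <- des$expression_program
  n_cells <- nrow(des$cells)
  for (loc in ref$te_loci$locus_id[1:5]) {
    expected <- sum(lam[loc, des$cells$stage])
    got <- sum(tt$source_feature == loc)
    expect_lt(abs(got - expected), 4 * sqrt(expected) + 1)
  }
})

test_that("chimera detection recovers planted links and nothing else", {
  sim <- tiny_simulation()
  ref <- tiny_reference()
  idx <- build_te_index(ref$te_loci)
  ch <- detect_chimeric(sim$alignments, idx, ref)
  truth_pairs <- unique(sim$truth[sim$truth$kind == "chimera",
                                  c("chimera_partner", "gene_id")])
  got <- unique(ch$table[, c("te_locus_id", "gene_id")])
  expect_equal(nrow(got), nrow(truth_pairs))
  expect_setequal(paste(got$te_locus_id, got$gene_id),
                  paste(truth_pairs$chimera_partner, truth_pairs$gene_id))
  expect_equal(sum(ch$table$umi_count),
               sum(sim$truth$kind == "chimera"))
  # two TE segments, no gene segment -> no link
  loci <- ref$te_loci[1:2, ]
  al <- scisote:::new_alignments(
    rep("rX|AAAACCCCGGGGTTTT|AAACCCGGGT", 2), loci$chrom, "+", 60L,
    list(cbind(start = loci$start[1], end = loci$end[1]),
         cbind(start = loci$start[2], end = loci$end[2])),
    is_primary = c(TRUE, FALSE), is_supplementary = c(FALSE, TRUE))
  expect_equal(nrow(detect_chimeric(al, idx, ref)$links), 0L)
})

test_that("rmsk tables round-trip", {
  ref <- tiny_reference()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_rmsk(ref$te_loci, p)
  back <- read_rmsk(p)
  o1 <- ref$te_loci[order(ref$te_loci$locus_id), ]
  o2 <- back[order(back$locus_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})
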