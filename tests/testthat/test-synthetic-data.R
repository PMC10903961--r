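test_that("toy reference satisfies its construction contract", {
  ref <- build_toy_reference(seed = 1, n_chromosomes = 1, n_genes = 5,
                             n_te_loci = 20)
  expect_equal(nrow(ref$genes), 5L)
  expect_equal(nrow(ref$te_loci), 20L)
  expect_false(anyDuplicated(ref$te_loci$locus_id) > 0)
  expect_true(all(table(ref$transcripts$gene_id) >= 1))
  expect_true(all(table(ref$transcripts$gene_id) <= 6))
  expect_true(validate_toy_reference(ref))
})

test_that("reference generation is deterministic to the byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_reference(build_toy_reference(seed = 7, n_genes = 4,
                                            n_te_loci = 10), d1)
  p2 <- write_reference(build_toy_reference(seed = 7, n_genes = 4,
                                            n_te_loci = 10), d2)
  expect_identical(readLines(p1[["gtf"]]), readLines(p2[["gtf"]]))
  expect_identical(readLines(p1[["rmsk"]]), readLines(p2[["rmsk"]]))
  expect_identical(readLines(p1[["genome"]]), readLines(p2[["genome"]]))
})

test_that("impossible placements raise a sizing error", {
  expect_error(build_toy_reference(seed = 2, n_genes = 10,
                                   chrom_length = 1000),
               "sizing error")
})

test_that("zero truncation rates yield only intact molecules", {
  ref <- tiny_reference()
  des <- experiment_design(
    ref, stages = c("A", "B"), cells_per_stage = 2, seed = 5,
    truncation_rates = data.frame(stage = c("A", "B"), p3 = 0, p5 = 0,
                                  p_internal = 0))
  sim <- simulate_molecules(ref, des)
  expect_true(all(sim$truth$truncation == "none"))
})

test_that("spike-in totals follow the Poisson expectation", {
  ref <- build_toy_reference(seed = 11, n_genes = 2, n_te_loci = 2,
                             n_spikein_genes = 1, spikein_base_copies = 50)
  des <- experiment_design(ref, stages = c("A"), cells_per_stage = 10,
                           seed = 3, include_spikeins = TRUE)
  sim <- simulate_molecules(ref, des)
  n_sp <- sum(sim$truth$kind == "spikein")
  expectation <- sum(ref$spikein_designs$copies_per_cell) * 10
  expect_lt(abs(n_sp - expectation), 3 * sqrt(expectation))
})

test_that("chimeric molecules carry a split truth alignment", {
  sim <- tiny_simulation()
  ch <- sim$truth[sim$truth$kind == "chimera", ]
  expect_gt(nrow(ch), 0)
  for (mid in ch$molecule_id) {
    seg <- sim$alignments[startsWith(sim$alignments$read_id, mid), ]
    seg <- seg[!grepl("_d", seg$read_id), ]
    expect_equal(sum(seg$is_supplementary), nrow(seg) / 2)
    supp <- seg[seg$is_supplementary, ]
    loc <- sim$truth$chimera_partner[sim$truth$molecule_id == mid]
    li <- tiny_reference()$te_loci
    li <- li[li$locus_id == loc, ]
    expect_true(all(supp$start >= li$start & supp$end <= li$end))
  }
})

test_that("truncated molecules respect the codon boundaries", {
  sim <- tiny_simulation()
  ref <- tiny_reference()
  tx <- ref$transcripts
  rownames(tx) <- tx$transcript_id
  t3 <- sim$truth[sim$truth$truncation == "three_prime" &
                    sim$truth$kind == "isoform", ]
  for (i in seq_len(nrow(t3))) {
    cd <- sim$cdna[[t3$molecule_id[i]]]
    tr <- tx[t3$source_feature[i], ]
    # molecule ends strictly before the annotated stop codon
    expect_lte(nchar(cd), tr$cds_end - 3)
  }
  t5 <- sim$truth[sim$truth$truncation == "five_prime" &
                    sim$truth$kind == "isoform", ]
  full <- transcript_sequences(ref, unique(t5$source_feature))
  for (i in seq_len(nrow(t5))) {
    cd <- sim$cdna[[t5$molecule_id[i]]]
    # molecule starts strictly after the start codon
    expect_lt(nchar(cd), nchar(full[[t5$source_feature[i]]]) -
                tx[t5$source_feature[i], "cds_start"] - 3 + 1)
  }
})

test_that("barcode corruption follows its contract", {
  sim <- tiny_simulation()
  r0 <- corrupt_barcodes(sim$reads, rate = 0, seed = 3)
  expect_identical(r0$observed_barcode, sim$reads$observed_barcode)
  r1 <- corrupt_barcodes(sim$reads, rate = 1, seed = 3)
  expect_true(all(hamming(r1$observed_barcode, r1$true_barcode) == 1L))
  # corrupted count equals an independent Bernoulli resampling, same seed
  r <- corrupt_barcodes(sim$reads, rate = 0.1, seed = 7)
  set.seed(7)
  expect_equal(attr(r, "n_corrupted"),
               sum(runif(nrow(sim$reads)) < 0.1))
})

test_that("simulation is deterministic and conserves molecules", {
  ref <- tiny_reference()
  des <- experiment_design(ref, stages = c("A", "B"), cells_per_stage = 2,
                           seed = 17)
  s1 <- simulate_molecules(ref, des)
  s2 <- simulate_molecules(ref, des)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$reads$sequence, s2$reads$sequence)
  # conservation: truth rows = distinct (barcode, umi, feature) molecules
  key <- paste(s1$truth$cell_barcode, s1$truth$umi, s1$truth$source_feature)
  expect_equal(length(unique(key)), nrow(s1$truth))
  expect_equal(length(unique(s1$reads$molecule_id)), nrow(s1$truth))
})

test_that("planted stage-specific expectations exceed off-peak by the fold", {
  ref <- tiny_reference()
  iso <- ref$transcripts$transcript_id[1:3]
  planted <- data.frame(feature_id = iso, peak_stage = "B", fold = 8)
  des <- experiment_design(ref, stages = c("A", "B", "C"),
                           cells_per_stage = 2, seed = 5,
                           planted_stage_specific = planted)
  lam <- des$expression_program
  expect_equal(unname(lam[iso, "B"] / lam[iso, "A"]), rep(8, 3))
})

test_that("truth tables round-trip through TSV", {
  sim <- tiny_simulation()
  d <- withr::local_tempdir()
  write_truth_tables(sim$truth, sim$design, d)
  back <- read_truth_tables(d)
  got <- back$molecule_truth
  # NA columns read back as NA; compare common structure
  expect_equal(nrow(got), nrow(sim$truth))
  expect_equal(got$molecule_id, sim$truth$molecule_id)
  expect_equal(got$umi, sim$truth$umi)
  # empty truth -> header-only file
  d2 <- withr::local_tempdir()
  write_truth_tables(sim$truth[0, ], sim$design, d2)
  expect_equal(length(readLines(file.path(d2, "molecule_truth.tsv"))), 1L)
})
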