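test_that("null features are not selected; planted jumps are", {
  s <- simulate_stage_counts(n_features = 300, n_planted = 30,
                             stages = paste0("S", 1:4),
                             cells_per_stage = 20, seed = 5)
  res <- stage_specific_features(s$sce)
  tr <- s$truth
  expect_gte(mean(res$selected[tr$planted]), 0.9)
  expect_lte(mean(res$selected[!tr$planted]), 0.05)
  # peak-stage cluster equals argmax of stage means (direct property)
  cp <- SummarizedExperiment::assay(s$sce, "cpm10")
  st <- SummarizedExperiment::colData(s$sce)$stage
  sm <- vapply(paste0("S", 1:4), function(g)
    Matrix::rowMeans(cp[, st == g, drop = FALSE]), numeric(nrow(cp)))
  expect_equal(res$peak_stage, paste0("S", 1:4)[apply(sm, 1, which.max)])
  rec <- tr$planted & res$selected
  expect_gte(mean(res$peak_stage[rec] == tr$peak_stage[rec]), 0.95)
  # clusters partition the selected set
  expect_true(all(!is.na(res$cluster[res$selected])))
  expect_true(all(is.na(res$cluster[!res$selected])))
})

test_that("identically distributed features stay unselected", {
  set.seed(9)
  m <- matrix(rpois(100 * 40, 10), nrow = 100,
              dimnames = list(sprintf("F%03d", 1:100), paste0("c", 1:40)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(m, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(stage = rep(c("A", "B"), each = 20),
                                   row.names = colnames(m)))
  res <- stage_specific_features(normalize_cpm10(sce))
  expect_lte(mean(res$selected), 0.02)
})

test_that("isoform diversity categories follow detected isoform counts", {
  counts <- rbind(
    G1.1 = c(3L, 1L),
    G2.1 = c(1L, 0L), G2.2 = c(2L, 0L), G2.3 = c(1L, 0L),
    G2.4 = c(1L, 0L), G2.5 = c(1L, 0L), G2.6 = c(1L, 0L))
  colnames(counts) <- c("c1", "c2")
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(stage = c("A", "A"),
                                   row.names = colnames(counts)))
  gm <- data.frame(feature_id = rownames(counts),
                   gene_id = sub("\\..*", "", rownames(counts)))
  dv <- isoform_diversity(sce, gm, stage_design(
    setNames(c("A", "A"), colnames(counts)), stages = c("A", "Z")))
  expect_equal(dv$n_genes[dv$category == "1"], 1L)
  expect_equal(dv$n_genes[dv$category == ">5"], 1L)
  expect_equal(sum(dv$n_genes), 2L)
  expect_equal(sum(dv$fraction), 1)
})

test_that("diversity fractions equal truth on simulated molecules", {
  ref <- tiny_reference()
  # intact molecules only: truncation would create extra (ISM) isoforms
  des <- experiment_design(
    ref, stages = c("oocyte", "zygote"), cells_per_stage = 4, seed = 404,
    truncation_rates = data.frame(stage = c("oocyte", "zygote"),
                                  p3 = 0, p5 = 0, p_internal = 0))
  sim <- simulate_molecules(ref, des)
  out <- run_toy_pipeline(sim, ref, isoform_min_cells = 1L)
  dv <- isoform_diversity(out$isoform_sce, out$isoform_gene_map)
  # recompute directly from the truth table for one stage
  st <- "oocyte"
  cells <- sim$design$cells$barcode[sim$design$cells$stage == st]
  tt <- sim$truth[sim$truth$kind == "isoform" &
                    sim$truth$cell_barcode %in% cells, ]
  truth_iso_per_gene <- tapply(tt$source_feature, tt$gene_id,
                               function(x) length(unique(x)))
  truth_cat <- table(factor(ifelse(truth_iso_per_gene > 5, ">5",
                                   truth_iso_per_gene),
                            levels = c("1", "2", "3", "4", "5", ">5")))
  got <- dv[dv$stage == st, ]
  expect_equal(got$n_genes, as.integer(truth_cat))
})

test_that("major-isoform ratio has the stated arithmetic and bounds", {
  counts <- rbind(G1.1 = c(8L, 0L), G1.2 = c(2L, 0L),
                  G2.1 = c(7L, 0L),
                  G3.1 = c(3L, 2L))  # G3 total 5: excluded (not > 5)
  colnames(counts) <- c("c1", "c2")
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(stage = c("A", "A"),
                                   row.names = colnames(counts)))
  gm <- data.frame(feature_id = rownames(counts),
                   gene_id = sub("\\..*", "", rownames(counts)))
  des <- stage_design(setNames(c("A", "A"), colnames(counts)),
                      stages = c("A", "Z"))
  mr <- major_isoform_ratio(sce, gm, des)
  expect_equal(mr$major_ratio[mr$gene_id == "G1"], 0.8)
  expect_equal(mr$major_ratio[mr$gene_id == "G2"], 1.0)
  expect_false("G3" %in% mr$gene_id)
  expect_true(all(mr$major_ratio > 0 & mr$major_ratio <= 1))
  expect_true(all((mr$major_ratio == 1) == (mr$n_isoforms == 1)))
})

test_that("switch detection flags planted switches, matches the exact test", {
  sw <- simulate_switch_counts(n_genes = 100, n_switch = 10,
                               umis_per_stage = 200, seed = 3)
  r <- detect_isoform_switch(sw$sce, sw$gene_map, c("A", "B"))
  truth <- sw$truth$gene_id[sw$truth$switched]
  det <- unique(r$gene_id[r$switched])
  expect_true(all(truth %in% det))
  # p-values equal the hypergeometric-tail oracle
  for (i in sample(nrow(r), 20)) {
    m <- SummarizedExperiment::assay(sw$sce, "counts")
    st <- SummarizedExperiment::colData(sw$sce)$stage
    a <- sum(m[r$isoform_id[i], st == "A"])
    c2 <- sum(m[r$isoform_id[i], st == "B"])
    sib <- sw$gene_map$feature_id[sw$gene_map$gene_id == r$gene_id[i]]
    gA <- sum(m[sib, st == "A"]); gB <- sum(m[sib, st == "B"])
    expect_equal(r$p_isoform[i], fisher_oracle(a, gA - a, c2, gB - c2),
                 tolerance = 1e-8)
  }
  # null fraction: dIF zero-ish cases never flagged
  null0 <- r[abs(r$dIF) < 0.1, ]
  expect_true(all(!null0$switched))
})

test_that("switch detection is symmetric in stage order", {
  sw <- simulate_switch_counts(n_genes = 50, n_switch = 5, seed = 13)
  r1 <- detect_isoform_switch(sw$sce, sw$gene_map, c("A", "B"))
  r2 <- detect_isoform_switch(sw$sce, sw$gene_map, c("B", "A"))
  expect_equal(r1$dIF, -r2$dIF)
  expect_equal(r1$isoform_q, r2$isoform_q)
  expect_equal(r1$gene_q, r2$gene_q)
  expect_equal(r1$switched, r2$switched)
})

test_that("low-coverage genes are skipped with a reason", {
  sw <- simulate_switch_counts(n_genes = 20, n_switch = 0,
                               umis_per_stage = 4, seed = 2)
  r <- detect_isoform_switch(sw$sce, sw$gene_map, c("A", "B"))
  expect_gt(nrow(attr(r, "skipped")), 0)
  expect_match(attr(r, "skipped")$reason[1], "UMIs")
})

test_that("TE-gene adjacency thresholds and correlations behave", {
  te_loci <- data.frame(locus_id = c("L1", "L2"), chrom = "chr1",
                        start = c(100000L, 150000L),
                        end = c(101000L, 151000L))
  genes <- data.frame(gene_id = c("Gnear", "Gmid", "Gfar", "Gtrans",
                                  "Gfill"),
                      chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
                      start = c(106000L, 401000L, 1200000L, 5000L,
                                1500000L),
                      end = c(110000L, 405000L, 1210000L, 9000L,
                              1510000L))
  set.seed(8)
  # equal per-cell totals on both sides, and Gnear's share of its matrix
  # equal to L1's share of its matrix, so the normalized profiles match
  base <- pmin(40L, pmax(8L, as.integer(rpois(30, 20))))
  tec <- rbind(L1 = base, L2 = 60L - base)
  colnames(tec) <- paste0("c", 1:30)
  gm <- rbind(Gnear = base, Gmid = 5L, Gfar = 5L, Gtrans = 5L,
              Gfill = 45L - base)
  colnames(gm) <- colnames(tec)
  mk <- function(m) SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(m, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(stage = rep("A", ncol(m)),
                                   row.names = colnames(m)))
  res <- te_gene_correlation(mk(tec), mk(gm), te_loci, genes)
  near <- res[res$te_locus_id == "L1" & res$gene_id == "Gnear", ]
  expect_equal(near$relation, "adjacent")                             # 5 kb
  expect_false("Gmid" %in% res$gene_id)                               # 300 kb
  expect_equal(unique(res$relation[res$gene_id == "Gfar"]),
               "non_adjacent")                                        # >1 Mb
  expect_equal(unique(res$relation[res$gene_id == "Gtrans"]),
               "non_adjacent")                                        # trans
  expect_equal(near$correlation, 1.0, tolerance = 1e-12)
  # loci below the activity threshold are not reported
  low <- tec; low["L1", ] <- 0L; low["L1", 1] <- 1L
  res2 <- te_gene_correlation(mk(low), mk(gm), te_loci, genes)
  expect_false("L1" %in% res2$te_locus_id)
})

test_that("coupled TE-gene simulation separates adjacent correlations", {
  ad <- simulate_coupled_te_gene(seed = 2)
  tg <- te_gene_correlation(ad$te_sce, ad$gene_sce,
                            ad$reference$te_loci, ad$reference$genes)
  a <- tg$correlation[tg$relation == "adjacent"]
  b <- tg$correlation[tg$relation == "non_adjacent"]
  expect_gt(length(a), 2)
  expect_gt(mean(a, na.rm = TRUE), mean(b, na.rm = TRUE))
  expect_lt(wilcox.test(a, b, alternative = "greater")$p.value, 0.01)
})
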