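test_that("rRNA fraction and fold enrichment follow their definitions", {
  cl <- data.frame(read_id = sprintf("r%d", 1:1000),
                   category = c(rep("rRNA", 940), rep("genome", 60)),
                   multi_mapped = FALSE)
  expect_equal(rrna_fraction(cl), 94)
  cl0 <- data.frame(read_id = "r1", category = "genome", multi_mapped = FALSE)
  expect_equal(rrna_fraction(cl0), 0)
  expect_error(rrna_fraction(data.frame(read_id = "r", category = "unmapped",
                                        multi_mapped = FALSE)), "zero mapped")
  expect_equal(fold_enrichment(50, 50), 1)
  expect_equal(fold_enrichment(94, 26.5), (1 - 0.265) / (1 - 0.94))
  expect_equal(fold_enrichment(94, 26.5), 12.25)
  expect_equal(fold_enrichment(90, 0), 10)
  expect_error(fold_enrichment(100, 5), "undefined")
  # identity and monotonicity
  for (p in c(0, 25, 60, 99)) expect_equal(fold_enrichment(p, p), 1)
  expect_true(fold_enrichment(90, 10) > fold_enrichment(90, 20))
})

test_that("CDS counting excludes multi-mapped and ambiguous reads", {
  features <- data.frame(seq_id = "chr", start = c(101, 301), end = c(200, 400),
                         strand = "+", feature_id = c("g1", "g2"))
  aln <- data.frame(
    read_id = c("in_g1", "multi", "straddle", "outside", "in_g2"),
    ref_id = "chr",
    pos = c(150, 150, 195, 250, 390),
    aln_len = c(20, 20, 120, 20, 20),   # straddle overlaps g1 and g2
    multi_mapped = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  counts <- cds_counts(aln, features)
  expect_equal(counts$count, c(1, 1))
  expect_equal(counts$length_nt, c(100, 100))
  # 1 bp overlap is enough
  aln1 <- data.frame(read_id = "edge", ref_id = "chr", pos = 81,
                     aln_len = 21, multi_mapped = FALSE)
  expect_equal(cds_counts(aln1, features)$count, c(1, 0))
})

test_that("TPM normalizes length-weighted rates to one million", {
  expect_equal(tpm(5, 100), 1e6)
  expect_equal(tpm(c(3, 3), c(50, 50)), c(5e5, 5e5))
  expect_equal(tpm(c(10, 20), c(100, 400)),
               c(2 / 3, 1 / 3) * 1e6, tolerance = 1e-9)
  expect_equal(tpm(c(0, 0), c(10, 10)), c(0, 0))
  set.seed(141)
  for (i in 1:20) {
    counts <- rpois(50, 40)
    lens <- sample(100:2000, 50)
    expect_equal(sum(tpm(counts, lens)), 1e6, tolerance = 1e-3)
  }
})

test_that("consistency statistics behave on identity, scaling and separation", {
  set.seed(151)
  counts <- data.frame(feature_id = sprintf("g%d", 1:40),
                       length_nt = sample(200:2000, 40),
                       count = rpois(40, 60))
  a <- expression_profile("a", counts)
  ident <- consistency(a, a)
  expect_equal(ident$pearson_r, 1)
  expect_equal(ident$spearman_rs, 1)
  expect_equal(ident$r_squared, 1)
  expect_equal(ident$mwu_effect_size, 0)
  expect_equal(ident$qq_pairs$quantile_a, ident$qq_pairs$quantile_b)
  # doubling all counts leaves TPM (hence everything) unchanged
  counts2 <- counts; counts2$count <- counts$count * 2
  b <- expression_profile("b", counts2)
  expect_equal(consistency(a, b)$pearson_r, 1)
  # complete separation gives |rank-biserial| = 1
  hi <- counts; hi$count <- hi$count + 1e4
  hi$length_nt <- 1  # force every transformed value above the other sample
  c_hi <- expression_profile("hi", hi)
  lo <- counts; lo$count <- 0
  c_lo <- expression_profile("lo", lo)
  # all-zero sample is constant after transform: correlation is undefined
  # there, but the rank-based effect size must still saturate
  sep <- suppressWarnings(consistency(c_hi, c_lo))
  expect_equal(abs(sep$mwu_effect_size), 1)
  expect_error(consistency(a, expression_profile("x", counts[1:2, ])),
               "CDS universe")
  expect_error(consistency(expression_profile("x", counts[1:2, ]),
                           expression_profile("y", counts[1:2, ])),
               "insufficient")
})

test_that("Spearman matches a rank-then-Pearson oracle on tied data", {
  set.seed(161)
  for (i in 1:100) {
    x <- sample(0:8, 30, replace = TRUE)   # heavy ties
    y <- x + sample(0:4, 30, replace = TRUE)
    expect_equal(stats::cor(x, y, method = "spearman"), spearman_oracle(x, y),
                 tolerance = 1e-12)
  }
  # via the consistency report (log10(TPM + 0.1) has ties at zero counts)
  counts_a <- data.frame(feature_id = sprintf("g%d", 1:30), length_nt = 100,
                         count = c(rep(0, 12), rpois(18, 30)))
  counts_b <- data.frame(feature_id = sprintf("g%d", 1:30), length_nt = 100,
                         count = c(rep(0, 10), rpois(20, 30)))
  pa <- expression_profile("a", counts_a)
  pb <- expression_profile("b", counts_b)
  expect_equal(consistency(pa, pb)$spearman_rs,
               spearman_oracle(log10(pa$tpm + 0.1), log10(pb$tpm + 0.1)),
               tolerance = 1e-12)
})

test_that("MDS reproduces sqrt(2 - 2 rs) distances for three samples", {
  set.seed(171)
  base <- data.frame(feature_id = sprintf("g%d", 1:60),
                     length_nt = sample(300:1500, 60),
                     count = rpois(60, 50))
  profiles <- lapply(1:3, function(i) {
    d <- base
    d$count <- rpois(60, base$count * runif(1, 0.5, 2))
    expression_profile(paste0("s", i), d)
  })
  ord <- mds_ordination(profiles)
  expect_equal(dim(ord$coords), c(3, 2))
  expect_true(all(abs(ord$distance - t(ord$distance)) < 1e-12))
  expect_equal(diag(ord$distance), rep(0, 3), ignore_attr = TRUE)
  # three points always embed exactly in 2-D
  emb <- as.matrix(stats::dist(ord$coords))
  expect_equal(max(abs(emb - ord$distance)), 0, tolerance = 1e-9)
  # sign canonicalization: first sample non-negative on both axes
  expect_true(all(ord$coords[1, ] >= -1e-12))
  # distance endpoints: rs = 1 -> 0, rs = 0 -> sqrt(2), rs = -1 -> 2
  expect_equal(sqrt(2 - 2 * 1), 0)
  expect_equal(sqrt(2 - 2 * 0), sqrt(2))
  expect_equal(sqrt(2 - 2 * -1), 2)
})

test_that("per-tile depletion efficiency applies the coverage pseudocount", {
  tiles <- data.frame(start = c(0, 50), end = c(50, 100))
  fold <- per_tile_depletion_efficiency(rep(100, 100), rep(5, 100),
                                        1000, 1000, tiles)
  expect_equal(fold$fold_change, rep(100.5 / 5.5, 2), tolerance = 1e-12)
  same <- per_tile_depletion_efficiency(rep(7, 100), rep(7, 100),
                                        500, 500, tiles)
  expect_equal(same$fold_change, rep(1, 2))
  zero <- per_tile_depletion_efficiency(rep(100, 100), rep(0, 100),
                                        1000, 1000, tiles)
  expect_true(all(is.finite(zero$fold_change)))
  expect_error(per_tile_depletion_efficiency(rep(1, 10), rep(1, 9), 1, 1,
                                             tiles), "differ in length")
})

test_that("mappability statistics split non-rRNA reads as defined", {
  cl <- data.frame(read_id = sprintf("r%d", 1:120),
                   category = c(rep("rRNA", 20), rep("genome", 80),
                                rep("unmapped", 20)),
                   multi_mapped = FALSE,
                   ref_id = c(rep("rr", 20), rep("chr", 80), rep(NA, 20)),
                   pos = c(rep(1, 100), rep(NA, 20)),
                   aln_len = c(rep(10, 100), rep(NA, 20)))
  cl$pos[21:80] <- 150   # 60 of 80 genome reads inside the CDS
  cl$pos[81:100] <- 500
  features <- data.frame(seq_id = "chr", start = 101, end = 200, strand = "+",
                         feature_id = "g1")
  ms <- mappability_stats(cl, features)
  expect_equal(ms$mappability_pct, 80)
  expect_equal(ms$cds_reads_pct, 75)
  all_in <- cl[cl$category == "genome", ]
  all_in$pos <- 150
  ms2 <- mappability_stats(all_in, features)
  expect_equal(ms2$mappability_pct, 100)
  expect_equal(ms2$cds_reads_pct, 100)
})

test_that("truth-table and SAM classification agree on simulator output", {
  org <- make_toy_organism(seed = 21, n_cds = 8)
  lib <- design_oligo_library(org$rrnas)
  pool <- simulate_pool(community_config(n_fragments = 4000, seed = 22), org)
  dep <- apply_depletion(pool, lib, model = depletion_model(p_max = 0.95),
                         seed = 23)
  prefix <- tempfile()
  paths <- emit_reads(dep$surviving, dep$truth, prefix, organism = org)
  survivors <- dep$truth[dep$truth$survived_depletion, ]
  via_truth <- classify_reads(truth = survivors)
  via_sam <- classify_reads(alignments = read_sam(paths[["sam"]]),
                            rrna_ids = c("toy_16S", "toy_23S"))
  expect_equal(rrna_fraction(via_truth), rrna_fraction(via_sam))
  m <- match(via_truth$read_id, via_sam$read_id)
  expect_equal(via_truth$category, via_sam$category[m])
  # end-to-end depletion report
  rep <- depletion_report("sim", classify_reads(truth = dep$truth), via_sam)
  expect_equal(rep$fold_enrichment,
               fold_enrichment(rep$rrna_pct_before, rep$rrna_pct_after))
  expect_equal(rep$mappability_pct, 100)
})
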