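test_that("toy organism generation is deterministic and within length specs", {
  o1 <- make_toy_organism(seed = 1, n_cds = 10)
  o2 <- make_toy_organism(seed = 1, n_cds = 10)
  expect_identical(o1, o2)
  expect_equal(nrow(o1$features), 10)
  l16 <- nchar(o1$rrnas[[1]]$seq)
  l23 <- nchar(o1$rrnas[[2]]$seq)
  expect_true(l16 >= 1400 && l16 <= 1600)
  expect_true(l23 >= 2800 && l23 <= 3000)
  # rRNA and CDS sequences sit at their annotated genome coordinates
  for (r in o1$rrnas) {
    s <- attr(r, "genome_start")
    expect_equal(substr(o1$genome$seq, s, s + nchar(r$seq) - 1), r$seq)
  }
  f <- o1$features
  for (i in seq_len(nrow(f)))
    expect_equal(substr(o1$genome$seq, f$start[i], f$end[i]), o1$cds_seqs[i])
  # byte-identical files across runs
  p1 <- tempfile(); p2 <- tempfile()
  write_toy_organism(o1, p1)
  write_toy_organism(make_toy_organism(seed = 1, n_cds = 10), p2)
  for (suffix in c("_genome.fasta", "_rrna.fasta", "_annot.gff3"))
    expect_identical(readLines(paste0(p1, suffix)),
                     readLines(paste0(p2, suffix)))
  # the GFF3 round-trips through the reader
  cds <- read_gff3(paste0(p1, "_annot.gff3"))
  expect_equal(cds$start, f$start)
  expect_equal(cds$feature_id, f$feature_id)
})

test_that("target mutation hits the configured divergence", {
  org <- make_toy_organism(seed = 2, n_cds = 2)
  r16 <- org$rrnas[[1]]
  expect_identical(mutate_target(r16, 0, seed = 3)$seq, r16$seq)
  m <- mutate_target(r16, 0.1, seed = 3)
  n_sub <- sum(strsplit(m$seq, "")[[1]] != strsplit(r16$seq, "")[[1]])
  # 99% binomial band for n in [1400, 1600] at p = 0.1 is contained in this
  band <- stats::qbinom(c(0.005, 0.995), nchar(r16$seq), 0.1)
  expect_true(n_sub >= band[1] && n_sub <= band[2])
  # measured alignment mismatch tracks the divergence within 2 points
  mm <- overall_mismatch_pct(align_pair(r16, m))
  expect_lt(abs(mm - 10), 2)
})

test_that("pool composition follows the configured fractions and origins", {
  org <- make_toy_organism(seed = 4, n_cds = 8)
  cfg <- community_config(rrna_fraction = 0.94, n_fragments = 100000,
                          seed = 5)
  pool <- simulate_pool(cfg, org)
  frac <- mean(pool$origin_class != "mRNA")
  band <- stats::qbinom(c(0.0005, 0.9995), 100000, 0.94) / 100000
  expect_true(frac >= band[1] && frac <= band[2])
  # 16S:23S split proportional to gene length
  l16 <- nchar(org$rrnas[[1]]$seq); l23 <- nchar(org$rrnas[[2]]$seq)
  n16 <- sum(pool$origin_class == "rRNA_16S")
  nrr <- sum(pool$origin_class != "mRNA")
  p16 <- l16 / (l16 + l23)
  band16 <- stats::qbinom(c(0.0005, 0.9995), nrr, p16) / nrr
  expect_true(n16 / nrr >= band16[1] && n16 / nrr <= band16[2])
  # every fragment substring-matches its recorded origin
  src <- c(stats::setNames(vapply(org$rrnas, `[[`, "", "seq"),
                           vapply(org$rrnas, `[[`, "", "id")),
           stats::setNames(org$cds_seqs, org$features$feature_id))
  idx <- sample(nrow(pool), 500)
  expect_true(all(vapply(idx, function(i)
    substr(src[[pool$origin_feature[i]]], pool$start[i],
           pool$start[i] + pool$length[i] - 1) == pool$seq[i], logical(1))))
  # no rRNA at all when the fraction is zero
  pool0 <- simulate_pool(community_config(rrna_fraction = 0,
                                          n_fragments = 500, seed = 6), org)
  expect_true(all(pool0$origin_class == "mRNA"))
})

test_that("depletion limit cases and threshold rules behave exactly", {
  org <- make_toy_organism(seed = 7, n_cds = 5)
  lib <- design_oligo_library(org$rrnas)
  cfg <- community_config(n_fragments = 5000, seed = 8)
  pool <- simulate_pool(cfg, org)
  # p_max = 1, cognate probes: every rRNA fragment removed, all mRNA kept
  dep <- apply_depletion(pool, lib, model = depletion_model(p_max = 1),
                         seed = 9)
  expect_true(all(dep$surviving$origin_class == "mRNA"))
  expect_equal(nrow(dep$truth), nrow(pool))
  expect_equal(sum(dep$truth$survived_depletion), nrow(dep$surviving))
  # probes locally ineffective (mismatch 30% >= threshold 25): background only
  sim30 <- data.frame(probe_id = lib$probes$probe_id, tile_mismatch_pct = 30)
  dep30 <- apply_depletion(pool, lib, similarity = sim30,
                           model = depletion_model(p_max = 1,
                                                   p_background = 0),
                           seed = 10)
  expect_equal(nrow(dep30$surviving), nrow(pool))
  expect_error(apply_depletion(pool, lib,
                               similarity = sim30[-1, , drop = FALSE],
                               seed = 1),
               "cover every probe")
})

test_that("post-depletion composition matches the closed-form mixture", {
  org <- make_toy_organism(seed = 11, n_cds = 10)
  lib <- design_oligo_library(org$rrnas)
  p <- 0.94; q <- 1 - 0.977
  cfg <- community_config(rrna_fraction = p, n_fragments = 50000, seed = 12)
  pool <- simulate_pool(cfg, org)
  dep <- apply_depletion(pool, lib, model = depletion_model(p_max = 1 - q),
                         seed = 13)
  obs <- mean(dep$surviving$origin_class != "mRNA")
  pred <- p * q / (p * q + 1 - p)
  se <- sqrt(pred * (1 - pred) / nrow(dep$surviving))
  expect_lt(abs(obs - pred), 3 * se + 0.01)
})

test_that("higher divergence never depletes more rRNA (monotonicity)", {
  org <- make_toy_organism(seed = 14, n_cds = 4)
  lib <- design_oligo_library(org$rrnas)
  cfg <- community_config(n_fragments = 8000, seed = 15)
  removed <- vapply(c(0, 0.1, 0.2, 0.3), function(div) {
    rr <- if (div > 0)
      lapply(org$rrnas, mutate_target, divergence = div, seed = 16) else
        org$rrnas
    sim <- do.call(rbind, lapply(1:2, function(g) {
      aln <- align_pair(org$rrnas[[g]], rr[[g]])
      per_probe_mismatch(aln, lib, gene = c("16S", "23S")[g])
    }))
    pool <- simulate_pool(cfg, org, rrnas = rr)
    dep <- apply_depletion(pool, lib, similarity = sim, seed = 17)
    sum(!dep$truth$survived_depletion)
  }, numeric(1))
  expect_true(all(diff(removed) <= 0))
})

test_that("read emission matches the truth table and SAM origins", {
  org <- make_toy_organism(seed = 18, n_cds = 5)
  lib <- design_oligo_library(org$rrnas)
  pool <- simulate_pool(community_config(n_fragments = 2000, seed = 19), org)
  dep <- apply_depletion(pool, lib, model = depletion_model(p_max = 0.9),
                         seed = 20)
  prefix <- tempfile()
  paths <- emit_reads(dep$surviving, dep$truth, prefix, organism = org)
  fq <- readLines(paths[["fastq"]])
  expect_equal(length(fq) / 4, nrow(dep$surviving))
  truth_back <- read.delim(paths[["truth"]], comment.char = "#")
  expect_equal(nrow(truth_back), nrow(pool))
  aln <- read_sam(paths[["sam"]])
  expect_equal(nrow(aln), nrow(dep$surviving))
  m <- match(aln$read_id, dep$surviving$frag_id)
  is_rrna <- dep$surviving$origin_class[m] != "mRNA"
  expect_equal(aln$pos[is_rrna], dep$surviving$start[m][is_rrna])
  expect_equal(aln$ref_id[is_rrna], dep$surviving$origin_feature[m][is_rrna])
  # mRNA reads placed on the genome at CDS offset
  cds_start <- org$features$start[match(dep$surviving$origin_feature[m],
                                        org$features$feature_id)]
  expect_equal(aln$pos[!is_rrna],
               (cds_start + dep$surviving$start[m] - 1)[!is_rrna])
})
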