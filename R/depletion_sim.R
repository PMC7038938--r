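# run code with a locally-seeded RNG stream, restoring global state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Community / pool configuration for the depletion simulator
#'
#' Defaults emulate a bacterial total-RNA pool after fragmentation: ~94% of
#' fragments are rRNA, fragment lengths ~N(60, 15) truncated at 25 nt.
#'
#' @param rrna_fraction Proportion of fragments that are rRNA (default 0.94).
#' @param n_fragments Number of fragments to draw.
#' @param fragment_len_mean,fragment_len_sd,fragment_len_min Fragment length
#'   distribution (truncated normal; defaults 60, 15, 25).
#' @param divergence Per-base substitution probability applied to the target
#'   rRNA relative to the probe-source rRNA (default 0, i.e. cognate species).
#' @param seed Integer seed.
#' @return List of class `community_config`.
#' @export
community_config <- function(rrna_fraction = 0.94, n_fragments = 100000L,
                             fragment_len_mean = 60, fragment_len_sd = 15,
                             fragment_len_min = 25L, divergence = 0,
                             seed = 1L) {
  stopifnot(rrna_fraction >= 0, rrna_fraction <= 1, n_fragments >= 1)
  structure(list(rrna_fraction = rrna_fraction,
                 n_fragments = as.integer(n_fragments),
                 fragment_len_mean = fragment_len_mean,
                 fragment_len_sd = fragment_len_sd,
                 fragment_len_min = as.integer(fragment_len_min),
                 divergence = divergence, seed = as.integer(seed)),
            class = "community_config")
}

#' Probabilistic model of probe-directed RNase H depletion
#'
#' A fragment overlapping (by at least `min_overlap` nt) the merged span of
#' probe tiles whose tile mismatch is below `local_threshold` percent is
#' removed with probability `p_max`; everything else (including mRNA) is
#' removed with probability `p_background`.
#'
#' @param p_max Removal probability for targetable fragments (default 0.98).
#' @param local_threshold Tile mismatch percent above which a probe is locally
#'   ineffective (default 25).
#' @param p_background Baseline removal probability (default 0).
#' @param min_overlap Minimum probe-fragment overlap in nt (default 20).
#' @return List of class `depletion_model`.
#' @export
depletion_model <- function(p_max = 0.98, local_threshold = 25,
                            p_background = 0, min_overlap = 20L) {
  stopifnot(p_background >= 0, p_background <= p_max, p_max <= 1)
  structure(list(p_max = p_max, local_threshold = local_threshold,
                 p_background = p_background,
                 min_overlap = as.integer(min_overlap)),
            class = "depletion_model")
}

#' Generate a toy organism (genome, rRNAs, CDS annotation)
#'
#' Builds a random genome carrying one 16S-like gene (1400-1600 nt), one
#' 23S-like gene (2800-3000 nt) and `n_cds` random CDSs separated by short
#' intergenic spacers, all on the plus strand, with a matching GFF3-style
#' annotation. Each CDS also receives a relative expression level drawn
#' log-normal(0, 1), so simulated mRNA pools carry the orders-of-magnitude
#' expression spread real transcriptomes have. Deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @param n_cds Number of CDSs (default 20).
#' @param cds_len_range Length range for CDSs (default 300-1500 nt).
#' @return List with `genome` (a [seq_record]), `rrnas` (list of two
#'   `seq_record`s tagged 16S/23S, with `genome_start` attributes),
#'   `features` (CDS data frame as from [read_gff3()]), `cds_seqs`, and
#'   `expression` (per-CDS relative abundance).
#' @export
make_toy_organism <- function(seed = 1L, n_cds = 20L,
                              cds_len_range = c(300L, 1500L)) {
  stopifnot(n_cds >= 1)
  with_seed(seed, {
    len16 <- sample(1400:1600, 1)
    len23 <- sample(2800:3000, 1)
    seq16 <- .random_dna(len16)
    seq23 <- .random_dna(len23)
    cds_lens <- sample(cds_len_range[1]:cds_len_range[2], n_cds, replace = TRUE)
    cds_seqs <- vapply(cds_lens, .random_dna, character(1))
    spacer <- function() .random_dna(sample(50:150, 1))
    parts <- character(0); starts <- integer(0); cursor <- 0L
    push <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      starts[[length(starts) + 1L]] <<- cursor + 1L
      cursor <<- cursor + nchar(s)
    }
    push(spacer())
    push(seq16); rrna16_start <- starts[length(starts)]
    push(spacer())
    push(seq23); rrna23_start <- starts[length(starts)]
    cds_starts <- integer(n_cds)
    for (i in seq_len(n_cds)) {
      push(spacer())
      push(cds_seqs[i]); cds_starts[i] <- starts[length(starts)]
    }
    push(spacer())
    genome <- seq_record("toy_genome", paste(parts, collapse = ""),
                         desc = "synthetic toy organism")
    r16 <- seq_record("toy_16S", seq16, desc = "16S ribosomal RNA (synthetic)")
    r23 <- seq_record("toy_23S", seq23, desc = "23S ribosomal RNA (synthetic)")
    attr(r16, "genome_start") <- rrna16_start
    attr(r23, "genome_start") <- rrna23_start
    features <- data.frame(
      seq_id = "toy_genome", start = cds_starts,
      end = cds_starts + cds_lens - 1L, strand = "+",
      feature_id = sprintf("cds_%03d", seq_len(n_cds)),
      stringsAsFactors = FALSE)
    expression <- stats::setNames(exp(stats::rnorm(n_cds, 0, 1)),
                                  features$feature_id)
    list(genome = genome, rrnas = list(r16, r23), features = features,
         cds_seqs = cds_seqs, expression = expression)
  })
}

#' Write a toy organism to FASTA + GFF3
#'
#' Emits `<prefix>_genome.fasta`, `<prefix>_rrna.fasta` and
#' `<prefix>_annot.gff3` (CDS and rRNA rows).
#'
#' @param organism A [make_toy_organism()] result.
#' @param prefix Output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_toy_organism <- function(organism, prefix) {
  gpath <- paste0(prefix, "_genome.fasta")
  rpath <- paste0(prefix, "_rrna.fasta")
  apath <- paste0(prefix, "_annot.gff3")
  write_fasta(list(organism$genome), gpath)
  write_fasta(organism$rrnas, rpath)
  con <- file(apath, open = "wb")
  writeLines("##gff-version 3", con)
  for (i in seq_along(organism$rrnas)) {
    r <- organism$rrnas[[i]]
    s <- attr(r, "genome_start")
    writeLines(sprintf("toy_genome\triboprobe\trRNA\t%d\t%d\t.\t+\t.\tID=%s",
                       s, s + nchar(r$seq) - 1L, r$id), con)
  }
  f <- organism$features
  writeLines(sprintf("toy_genome\triboprobe\tCDS\t%d\t%d\t.\t%s\t.\tID=%s",
                     f$start, f$end, f$strand, f$feature_id), con)
  close(con)
  invisible(c(gpath, rpath, apath))
}

#' Mutate a target rRNA away from the probe source
#'
#' Substitutes each base independently (to one of the three other bases) with
#' probability `divergence`, emulating the sequence divergence between the
#' species a probe library was designed for and a related target species.
#'
#' @param rrna A [seq_record].
#' @param divergence Per-base substitution probability in `[0, 0.5]`.
#' @param seed Integer seed.
#' @return A mutated `seq_record` (id suffixed `_mut`, gene tag preserved).
#' @export
mutate_target <- function(rrna, divergence, seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 0.5)
  with_seed(seed, {
    chars <- strsplit(rrna$seq, "")[[1]]
    hit <- stats::runif(length(chars)) < divergence
    if (any(hit)) {
      alt <- c("A", "C", "G", "T")
      chars[hit] <- vapply(chars[hit], function(b)
        sample(setdiff(alt, b), 1), character(1))
    }
    out <- seq_record(paste0(rrna$id, "_mut"), paste(chars, collapse = ""),
                      desc = rrna$desc)
    attr(out, "n_substitutions") <- sum(hit)
    out
  })
}

#' Simulate a fragmented total-RNA pool
#'
#' Draws `n_fragments` fragments: rRNA with probability `rrna_fraction`
#' (split between 16S and 23S in proportion to gene length), otherwise mRNA
#' from a CDS chosen with probability proportional to CDS length times its
#' relative expression level (`abundance = NULL` gives pure length
#' weighting, i.e. a flat transcriptome). Fragment
#' length is truncated-normal (capped at the source length); the start is
#' uniform over the positions where the fragment fits inside the source, so
#' no fragment is shorter than the configured minimum.
#'
#' @param config A [community_config()].
#' @param organism A [make_toy_organism()] result; its rRNAs may be replaced
#'   by diverged targets via `rrnas`.
#' @param rrnas Optional list of two `seq_record`s overriding
#'   `organism$rrnas` (e.g. from [mutate_target()]).
#' @param abundance Per-CDS relative expression weights (default
#'   `organism$expression`); `NULL` for length-only weighting.
#' @return Data frame of fragments: `frag_id`, `origin_class`
#'   (`rRNA_16S`/`rRNA_23S`/`mRNA`), `origin_feature`, `start` (1-based on
#'   the source), `length`, `seq`.
#' @export
simulate_pool <- function(config, organism, rrnas = NULL,
                          abundance = organism$expression) {
  if (is.null(rrnas)) rrnas <- organism$rrnas
  r16 <- rrnas[[1]]; r23 <- rrnas[[2]]
  l16 <- nchar(r16$seq); l23 <- nchar(r23$seq)
  cds_lens <- organism$features$end - organism$features$start + 1L
  if (is.null(abundance)) abundance <- rep(1, length(cds_lens))
  cds_w <- cds_lens * abundance
  with_seed(config$seed, {
    n <- config$n_fragments
    is_rrna <- stats::runif(n) < config$rrna_fraction
    gene16 <- stats::runif(n) < l16 / (l16 + l23)
    origin_class <- ifelse(is_rrna, ifelse(gene16, "rRNA_16S", "rRNA_23S"),
                           "mRNA")
    cds_pick <- sample(seq_along(cds_lens), n, replace = TRUE,
                       prob = cds_w / sum(cds_w))
    origin_feature <- ifelse(origin_class == "rRNA_16S", r16$id,
                      ifelse(origin_class == "rRNA_23S", r23$id,
                             organism$features$feature_id[cds_pick]))
    src_len <- ifelse(origin_class == "rRNA_16S", l16,
               ifelse(origin_class == "rRNA_23S", l23, cds_lens[cds_pick]))
    want_len <- pmax(config$fragment_len_min,
                     round(stats::rnorm(n, config$fragment_len_mean,
                                        config$fragment_len_sd)))
    len <- pmin(as.integer(want_len), src_len)
    start <- 1L + floor(stats::runif(n) * (src_len - len + 1L))
    src_seq <- ifelse(origin_class == "rRNA_16S", r16$seq,
               ifelse(origin_class == "rRNA_23S", r23$seq,
                      organism$cds_seqs[cds_pick]))
    data.frame(frag_id = sprintf("frag_%07d", seq_len(n)),
               origin_class = origin_class, origin_feature = origin_feature,
               start = start, length = len,
               seq = substring(src_seq, start, start + len - 1L),
               stringsAsFactors = FALSE)
  })
}

#' Apply probe-directed depletion to a fragment pool
#'
#' rRNA fragments overlapping at least `model$min_overlap` nt of the merged
#' span of locally effective probe tiles (tile mismatch below
#' `model$local_threshold`) are removed with probability `model$p_max`;
#' all other fragments with probability `model$p_background`.
#'
#' @param fragments [simulate_pool()] output.
#' @param library A [probe_library].
#' @param similarity Data frame `probe_id`, `tile_mismatch_pct` covering every
#'   probe (all zero for the cognate species); `NULL` means cognate (0).
#' @param model A [depletion_model()].
#' @param seed Integer seed for the removal draws.
#' @return List with `surviving` (fragment data frame) and `truth` (per-read
#'   truth table: `read_id`, `origin_class`, `origin_feature`,
#'   `survived_depletion`).
#' @export
apply_depletion <- function(fragments, library, similarity = NULL,
                            model = depletion_model(), seed = 1L) {
  p <- library$probes
  if (is.null(similarity))
    similarity <- data.frame(probe_id = p$probe_id, tile_mismatch_pct = 0)
  mm <- similarity$tile_mismatch_pct[match(p$probe_id, similarity$probe_id)]
  if (anyNA(mm))
    stop("similarity must cover every probe in the library")
  eligible <- mm < model$local_threshold
  # merged spans of eligible tiles, per gene
  spans <- lapply(split(p[eligible, , drop = FALSE], p$gene[eligible]),
                  function(g) {
    if (!nrow(g)) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(g$tile_start + 1L, g$tile_end))
    data.frame(start = BiocGenerics::start(ir), end = BiocGenerics::end(ir))
  })
  frag_targetable <- function(cls, start, len) {
    gene <- if (cls == "rRNA_16S") "16S" else if (cls == "rRNA_23S") "23S" else
      return(FALSE)
    sp <- spans[[gene]]
    if (is.null(sp)) return(FALSE)
    ov <- pmin(sp$end, start + len - 1L) - pmax(sp$start, start) + 1L
    any(ov >= model$min_overlap)
  }
  targetable <- mapply(frag_targetable, fragments$origin_class,
                       fragments$start, fragments$length)
  with_seed(seed, {
    p_remove <- ifelse(targetable, model$p_max, model$p_background)
    removed <- stats::runif(nrow(fragments)) < p_remove
    truth <- data.frame(read_id = fragments$frag_id,
                        origin_class = fragments$origin_class,
                        origin_feature = fragments$origin_feature,
                        survived_depletion = !removed,
                        stringsAsFactors = FALSE)
    list(surviving = fragments[!removed, , drop = FALSE], truth = truth)
  })
}

#' Emit reads and truth table for a depleted pool
#'
#' Writes one FASTQ read per surviving fragment (fixed quality `I`), the full
#' truth table as TSV (one row per fragment, survivors and removed), and
#' optionally a SAM file giving each surviving read's known origin as an
#' alignment against the rRNA genes and the toy genome.
#'
#' @param surviving Surviving fragments ([apply_depletion()] `$surviving`).
#' @param truth Truth table ([apply_depletion()] `$truth`).
#' @param out_prefix Output path prefix.
#' @param organism Optional [make_toy_organism()] result; when supplied a SAM
#'   file is written (rRNA-origin reads against the rRNA references,
#'   mRNA-origin reads against the genome at their CDS position).
#' @return Named character vector of written paths, invisibly.
#' @export
emit_reads <- function(surviving, truth, out_prefix, organism = NULL) {
  stopifnot(nrow(surviving) >= 1)
  fq <- paste0(out_prefix, "_reads.fastq")
  con <- file(fq, open = "wb")
  qual <- vapply(surviving$length, function(l)
    paste(rep("I", l), collapse = ""), character(1))
  writeLines(paste0("@", surviving$frag_id, "\n", surviving$seq, "\n+\n", qual),
             con)
  close(con)
  tt <- paste0(out_prefix, "_truth.tsv")
  write_tsv(truth, tt)
  paths <- c(fastq = fq, truth = tt)
  if (!is.null(organism)) {
    sam <- paste0(out_prefix, "_reads.sam")
    con <- file(sam, open = "wb")
    for (r in organism$rrnas)
      writeLines(sprintf("@SQ\tSN:%s\tLN:%d", r$id, nchar(r$seq)), con)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", organism$genome$id,
                       nchar(organism$genome$seq)), con)
    is_rrna <- surviving$origin_class != "mRNA"
    ref <- ifelse(is_rrna, surviving$origin_feature, organism$genome$id)
    cds_start <- organism$features$start[match(surviving$origin_feature,
                                               organism$features$feature_id)]
    pos <- ifelse(is_rrna, surviving$start, cds_start + surviving$start - 1L)
    writeLines(sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                       surviving$frag_id, ref, pos, surviving$length,
                       surviving$seq, qual), con)
    close(con)
    paths <- c(paths, sam = sam)
  }
  invisible(paths)
}
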