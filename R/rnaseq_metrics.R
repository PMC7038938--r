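#' Classify reads as rRNA / genome-mapped / unmapped
#'
#' Two input routes, mirroring a two-pass alignment pipeline (reads are
#' aligned to the 16S/23S references first; the remainder to the genome):
#' either a simulator truth table, or SAM alignment records plus the set of
#' rRNA reference names.
#'
#' @param truth Truth-table data frame (`read_id`, `origin_class`, ...)
#'   restricted to surviving reads, or `NULL`.
#' @param alignments [read_sam()] data frame, or `NULL`.
#' @param rrna_ids Reference names counting as rRNA (SAM route).
#' @return Data frame `read_id`, `category`
#'   (`rRNA`/`genome`/`unmapped`), `multi_mapped`, plus `ref_id`, `pos`,
#'   `aln_len` when available.
#' @export
classify_reads <- function(truth = NULL, alignments = NULL,
                           rrna_ids = character()) {
  if (!is.null(truth)) {
    return(data.frame(read_id = truth$read_id,
                      category = ifelse(truth$origin_class == "mRNA",
                                        "genome", "rRNA"),
                      multi_mapped = FALSE, stringsAsFactors = FALSE))
  }
  if (is.null(alignments)) stop("provide a truth table or SAM alignments")
  data.frame(read_id = alignments$read_id,
             category = ifelse(is.na(alignments$ref_id), "unmapped",
                        ifelse(alignments$ref_id %in% rrna_ids, "rRNA",
                               "genome")),
             multi_mapped = alignments$multi_mapped,
             ref_id = alignments$ref_id, pos = alignments$pos,
             aln_len = alignments$aln_len, stringsAsFactors = FALSE)
}

#' Percentage of mapped reads originating from rRNA
#'
#' 100 x reads mapped to rRNA / total mapped reads.
#'
#' @param classified [classify_reads()] output.
#' @return Percent.
#' @export
rrna_fraction <- function(classified) {
  mapped <- classified$category != "unmapped"
  if (!sum(mapped)) stop("undefined: zero mapped reads")
  100 * sum(classified$category == "rRNA") / sum(mapped)
}

#' Fold enrichment of non-rRNA reads
#'
#' `(1 - p_after/100) / (1 - p_before/100)` where p is the rRNA read
#' percentage before/after depletion.
#'
#' @param p_before,p_after rRNA read percentages.
#' @return Fold-enrichment ratio.
#' @export
fold_enrichment <- function(p_before, p_after) {
  if (p_before >= 100) stop("undefined: p_before is 100%")
  (1 - p_after / 100) / (1 - p_before / 100)
}

#' Unique-read counts per CDS
#'
#' A read counts for a CDS when its alignment overlaps the CDS by at least
#' 1 bp on either strand. Multi-mapped reads are excluded; reads overlapping
#' two or more CDSs are ambiguous and excluded from all.
#'
#' @param alignments [read_sam()]-style data frame (genome alignments).
#' @param features CDS data frame ([read_gff3()] output).
#' @return Data frame `feature_id`, `length_nt`, `count` (one row per CDS,
#'   in `features` order).
#' @export
cds_counts <- function(alignments, features) {
  a <- alignments[!is.na(alignments$ref_id) & !alignments$multi_mapped, ,
                  drop = FALSE]
  counts <- integer(nrow(features))
  if (nrow(a)) {
    reads <- GenomicRanges::GRanges(a$ref_id,
               IRanges::IRanges(a$pos, width = a$aln_len))
    cds <- GenomicRanges::GRanges(features$seq_id,
             IRanges::IRanges(features$start, features$end))
    ov <- GenomicRanges::findOverlaps(reads, cds, minoverlap = 1L,
                                      ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    n_cds_per_read <- table(qh)
    unambiguous <- as.integer(names(n_cds_per_read)[n_cds_per_read == 1L])
    keep <- qh %in% unambiguous
    tab <- table(sh[keep])
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  data.frame(feature_id = features$feature_id,
             length_nt = features$end - features$start + 1L,
             count = counts, stringsAsFactors = FALSE)
}

#' Transcripts per million
#'
#' `rate_i = count_i / length_i; tpm_i = 1e6 * rate_i / sum(rate)`. All-zero
#' counts yield all-zero TPM.
#'
#' @param counts Integer counts per CDS.
#' @param lengths CDS lengths in nt (all >= 1).
#' @return Numeric TPM vector.
#' @export
tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), all(lengths >= 1))
  rate <- counts / lengths
  if (sum(rate) == 0) return(rep(0, length(counts)))
  1e6 * rate / sum(rate)
}

#' Expression profile for one sample
#'
#' @param sample_id Sample identifier.
#' @param counts [cds_counts()] output (or a data frame with `feature_id`,
#'   `length_nt`, `count`).
#' @return Data frame of class `expression_profile` with columns
#'   `feature_id`, `count`, `length_nt`, `tpm`; attribute `sample_id`.
#' @export
expression_profile <- function(sample_id, counts) {
  out <- data.frame(feature_id = counts$feature_id, count = counts$count,
                    length_nt = counts$length_nt,
                    tpm = tpm(counts$count, counts$length_nt),
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("expression_profile", "data.frame")
  out
}

# Mann-Whitney U statistic of x vs y (ties get average rank)
.mwu_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Transcriptome consistency between two samples
#'
#' Correlations of `log10(TPM + 0.1)` (Pearson, Spearman with average ranks,
#' and R-squared as the square of Pearson r), matched order statistics for
#' Q-Q comparison, and Mann-Whitney effect sizes (rank-biserial
#' `2U/(n_a n_b) - 1` and common-language `U/(n_a n_b)`).
#'
#' @param profile_a,profile_b [expression_profile()]s over the same CDSs.
#' @return List of class `consistency_report`: `pearson_r`, `spearman_rs`,
#'   `r_squared`, `qq_pairs` (data frame `quantile_a`, `quantile_b`),
#'   `mwu_effect_size` (rank-biserial), `mwu_common_language`.
#' @export
consistency <- function(profile_a, profile_b) {
  if (!identical(profile_a$feature_id, profile_b$feature_id))
    stop("profiles must share the same CDS universe (same order)")
  if (nrow(profile_a) < 3L) stop("insufficient data: need >= 3 CDSs")
  x <- log10(profile_a$tpm + 0.1)
  y <- log10(profile_b$tpm + 0.1)
  r <- stats::cor(x, y, method = "pearson")
  rs <- stats::cor(x, y, method = "spearman")
  u <- .mwu_u(x, y)
  n2 <- as.numeric(length(x)) * length(y)
  structure(list(pearson_r = r, spearman_rs = rs, r_squared = r^2,
                 qq_pairs = data.frame(quantile_a = sort(x),
                                       quantile_b = sort(y)),
                 mwu_effect_size = 2 * u / n2 - 1,
                 mwu_common_language = u / n2),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(paste0("<consistency_report> r = %.4f, rs = %.4f, R2 = %.4f, ",
                     "rank-biserial = %.4f\n"),
              x$pearson_r, x$spearman_rs, x$r_squared, x$mwu_effect_size))
  invisible(x)
}

#' Classical MDS ordination of expression profiles
#'
#' Pairwise Spearman correlations `rs` of `log10(TPM + 0.1)` are turned into
#' distances `d = sqrt(2 - 2 rs)` and embedded by classical (Torgerson) MDS.
#' Axis signs are canonicalized so the first sample has non-negative
#' coordinates on each axis.
#'
#' @param profiles List of >= 3 [expression_profile()]s (same CDS universe).
#' @return List of class `ordination_result`: `sample_ids`, `distance`
#'   (matrix), `coords` (n x 2, or n x 1 with a warning when the second
#'   eigenvalue is non-positive), `eig`.
#' @export
mds_ordination <- function(profiles) {
  if (length(profiles) < 3L) stop("need >= 3 profiles")
  ids <- vapply(profiles, function(p)
    attr(p, "sample_id") %||% "sample", character(1))
  ids <- make.unique(ids)
  xs <- vapply(profiles, function(p) log10(p$tpm + 0.1),
               numeric(nrow(profiles[[1]])))
  rs <- stats::cor(xs, method = "spearman")
  d <- sqrt(pmax(2 - 2 * rs, 0))  # first arg keeps the matrix shape
  dimnames(d) <- list(ids, ids)
  fit <- stats::cmdscale(stats::as.dist(d), k = 2, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < 2L || fit$eig[2] <= 0) {
    warning("second MDS eigenvalue non-positive; returning 1-D ordination")
    coords <- coords[, 1, drop = FALSE]
  }
  for (j in seq_len(ncol(coords))) {
    pivot <- which(abs(coords[, j]) > 1e-12)[1]
    if (!is.na(pivot) && coords[pivot, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- ids
  structure(list(sample_ids = ids, distance = d, coords = coords,
                 eig = fit$eig), class = "ordination_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-tile depletion efficiency (rRNA coverage fold change)
#'
#' Per-base coverage is given a pseudocount of 0.5, normalized to each
#' sample's non-rRNA mapped total, and the per-base fold change
#' (undepleted / depleted) is averaged within each probe tile.
#'
#' @param cov_undepleted,cov_depleted Per-base coverage vectors spanning the
#'   full rRNA.
#' @param norm_undepleted,norm_depleted Non-rRNA mapped read totals.
#' @param tiles Data frame with 0-based half-open `start`, `end`
#'   ([tile_sequence()] output).
#' @param pseudocount Added to raw coverage before normalizing (default 0.5).
#' @return Data frame `tile`, `start`, `end`, `fold_change`.
#' @export
per_tile_depletion_efficiency <- function(cov_undepleted, cov_depleted,
                                          norm_undepleted, norm_depleted,
                                          tiles, pseudocount = 0.5) {
  if (length(cov_undepleted) != length(cov_depleted))
    stop("consistency error: coverage vectors differ in length")
  if (max(tiles$end) != length(cov_undepleted))
    stop("consistency error: tiles do not span the coverage vector")
  cu <- (cov_undepleted + pseudocount) / norm_undepleted
  cd <- (cov_depleted + pseudocount) / norm_depleted
  fold <- cu / cd
  data.frame(tile = seq_len(nrow(tiles)), start = tiles$start,
             end = tiles$end,
             fold_change = vapply(seq_len(nrow(tiles)), function(i)
               mean(fold[(tiles$start[i] + 1L):tiles$end[i]]), numeric(1)))
}

#' Mappability and CDS-read statistics for non-rRNA reads
#'
#' `mappability_pct` = 100 x genome-mapped non-rRNA reads / all non-rRNA
#' reads; `cds_reads_pct` = 100 x CDS-overlapping reads / genome-mapped
#' non-rRNA reads.
#'
#' @param classified [classify_reads()] output.
#' @param features Optional CDS data frame; when supplied (and alignment
#'   coordinates are present) `cds_reads_pct` is computed, else `NA`.
#' @return List with `mappability_pct`, `cds_reads_pct`.
#' @export
mappability_stats <- function(classified, features = NULL) {
  non_rrna <- classified[classified$category != "rRNA", , drop = FALSE]
  if (!nrow(non_rrna)) stop("undefined: no non-rRNA reads")
  mapped <- non_rrna[non_rrna$category == "genome", , drop = FALSE]
  mappability_pct <- 100 * nrow(mapped) / nrow(non_rrna)
  cds_reads_pct <- NA_real_
  if (!is.null(features) && nrow(mapped) &&
      all(c("ref_id", "pos", "aln_len") %in% colnames(mapped))) {
    reads <- GenomicRanges::GRanges(mapped$ref_id,
               IRanges::IRanges(mapped$pos, width = mapped$aln_len))
    cds <- GenomicRanges::GRanges(features$seq_id,
             IRanges::IRanges(features$start, features$end))
    in_cds <- GenomicRanges::countOverlaps(reads, cds,
                                           ignore.strand = TRUE) > 0
    cds_reads_pct <- 100 * sum(in_cds) / nrow(mapped)
  }
  list(mappability_pct = mappability_pct, cds_reads_pct = cds_reads_pct)
}

#' Depletion report for a before/after sample pair
#'
#' @param sample_id Identifier for the depleted sample.
#' @param classified_before,classified_after [classify_reads()] outputs for
#'   the undepleted and depleted samples.
#' @param features Optional CDS data frame for `cds_reads_pct`.
#' @return List of class `depletion_report`: `sample_id`, `rrna_pct_before`,
#'   `rrna_pct_after`, `fold_enrichment`, `mappability_pct`, `cds_reads_pct`.
#' @export
depletion_report <- function(sample_id, classified_before, classified_after,
                             features = NULL) {
  pb <- rrna_fraction(classified_before)
  pa <- rrna_fraction(classified_after)
  ms <- mappability_stats(classified_after, features)
  structure(list(sample_id = sample_id, rrna_pct_before = pb,
                 rrna_pct_after = pa,
                 fold_enrichment = fold_enrichment(pb, pa),
                 mappability_pct = ms$mappability_pct,
                 cds_reads_pct = ms$cds_reads_pct),
            class = "depletion_report")
}

#' @export
print.depletion_report <- function(x, ...) {
  cat(sprintf(
    "<depletion_report> %s: rRNA %.1f%% -> %.1f%% (%.2f-fold enrichment)\n",
    x$sample_id, x$rrna_pct_before, x$rrna_pct_after, x$fold_enrichment))
  invisible(x)
}
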