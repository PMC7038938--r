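#' Build an exact k-mer seed index over a transcriptome
#'
#' Postings map every k-mer of every transcript, on both strands, to
#' `(transcript, position, strand)`. Used to trigger banded extension in
#' [screen_offtargets()]; any probe within the mismatch budget of a window
#' must share at least one exact k-mer with it when the probe is at least
#' `k + max_mismatches` long (pigeonhole).
#'
#' @param transcriptome List of [seq_record]s.
#' @param k Seed length (default 12, minimum 8).
#' @return An object of class `seed_index` (environment keyed by k-mer, each
#'   value a data frame of postings with columns `tx`, `pos`, `strand`).
#' @export
build_seed_index <- function(transcriptome, k = 12L) {
  k <- as.integer(k)
  if (k < 8L) stop("seed k must be >= 8")
  env <- new.env(hash = TRUE, parent = emptyenv())
  posts <- list()
  for (r in transcriptome) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") r$seq else reverse_complement(r$seq)
      n <- nchar(s)
      if (n < k) next
      posts[[length(posts) + 1L]] <- data.frame(
        kmer = substring(s, 1:(n - k + 1L), k:n),
        tx = r$id, pos = 1:(n - k + 1L), strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  if (length(posts)) {
    all <- do.call(rbind, posts)
    idx_by <- split(seq_len(nrow(all)), all$kmer)
    for (key in names(idx_by))
      env[[key]] <- all[idx_by[[key]], c("tx", "pos", "strand"), drop = FALSE]
  }
  structure(list(index = env, k = k,
                 tx_len = stats::setNames(
                   vapply(transcriptome, function(r) nchar(r$seq), integer(1)),
                   vapply(transcriptome, `[[`, "", "id"))),
            class = "seed_index")
}

#' Number of postings stored in a seed index
#' @param idx A [build_seed_index()] result.
#' @return Integer posting count.
#' @export
seed_index_size <- function(idx) {
  keys <- ls(idx$index)
  if (!length(keys)) return(0L)
  sum(vapply(keys, function(k) nrow(idx$index[[k]]), integer(1)))
}

# Exhaustive semi-global scan: unit-cost edit distance (substitutions + gap
# columns) of the full-length query against every window of the transcript.
# Row-vectorized DP over query positions; D[j] after the last row is the best
# distance of an alignment consuming the whole query and ending at transcript
# position j. The horizontal (gap-in-query) transition is folded in with a
# cummin over A[j] - j, which equals min_{j' <= j} A[j'] + (j - j').
.semiglobal_end_distances <- function(query, txseq) {
  qc <- strsplit(query, "")[[1]]
  tc <- strsplit(txseq, "")[[1]]
  L <- length(tc)
  D <- rep(0, L)                       # row 0: free start anywhere
  for (i in seq_along(qc)) {
    sub_cost <- as.integer(tc != qc[i])
    A <- pmin(c(i - 1, D[-L]) + sub_cost, D + 1)
    D <- pmin(i + seq_len(L), cummin(A - seq_len(L)) + seq_len(L))
  }
  D
}

# best full-query window around end position `end`: re-derive the start and
# exact distance by Levenshtein over candidate windows ending at `end`
.window_at_end <- function(query, txseq, end, band) {
  np <- nchar(query)
  starts <- max(1L, end - np + 1L - band):min(end, end - np + 1L + band)
  wins <- substring(txseq, starts, end)
  d <- utils::adist(query, wins)[1, ]
  i <- which.min(d)
  list(dist = d[i], start = starts[i], end = end)
}

#' Screen a probe library for off-target transcripts
#'
#' For each probe, finds every transcript (excluding the cognate rRNAs) with
#' a window to which the probe — or its reverse complement — aligns
#' end-to-end with at most `max_mismatches` substitutions plus gap columns.
#' The search is exhaustive within the threshold: a semi-global unit-cost
#' alignment of the full-length probe is scanned over every transcript
#' position, so every within-budget hit is reported (no heuristic misses).
#' The exact k-mer index ([build_seed_index()]) is consulted to skip
#' transcripts sharing no seed with the query, but only for queries of at
#' least `(max_mismatches + 1) * k` nt, where an exact shared k-mer is
#' guaranteed by pigeonhole; shorter queries are always scanned in full.
#' One best hit is kept per (probe, transcript, locus).
#'
#' Hits are annotated with strand: `"sense"` means the probe is antisense to
#' the transcript (the reverse complement of the probe matches the transcript
#' as written), which is the configuration in which RNase H would cleave that
#' transcript.
#'
#' @param library A [probe_library].
#' @param transcriptome List of [seq_record]s.
#' @param rrna_ids Character vector of transcript ids to exclude (the cognate
#'   rRNAs).
#' @param max_mismatches Mismatch budget (default 8).
#' @param k Seed length (default 12).
#' @return Data frame of hits: `probe_id`, `transcript_id`, `mismatches`,
#'   `target_start`, `target_end` (1-based inclusive), `strand`.
#' @export
screen_offtargets <- function(library, transcriptome, rrna_ids = character(),
                              max_mismatches = 8L, k = 12L) {
  if (!length(library$probes) || nrow(library$probes) == 0L)
    stop("usage error: empty probe library")
  keep <- vapply(transcriptome, function(r) !(r$id %in% rrna_ids), logical(1))
  transcriptome <- transcriptome[keep]
  hits <- list()
  if (!length(transcriptome)) return(.empty_hits())
  idx <- build_seed_index(transcriptome, k = k)
  txseq <- stats::setNames(vapply(transcriptome, `[[`, "", "seq"),
                           vapply(transcriptome, `[[`, "", "id"))
  band <- as.integer(max_mismatches)
  for (pi in seq_len(nrow(library$probes))) {
    probe <- library$probes$seq[pi]
    pid <- library$probes$probe_id[pi]
    np <- nchar(probe)
    # query with the probe's reverse complement = "sense" configuration
    # (probe antisense to the transcript), and the probe itself = "antisense".
    for (qstrand in c("sense", "antisense")) {
      query <- if (qstrand == "sense") reverse_complement(probe) else probe
      candidates <- names(txseq)
      if (np >= (band + 1L) * idx$k) {
        seeded <- .seed_loci(query, idx, band)
        candidates <- intersect(candidates, seeded$tx)
      }
      for (tx in candidates) {
        ends <- .semiglobal_end_distances(query, txseq[[tx]])
        hit_ends <- which(ends <= max_mismatches)
        if (!length(hit_ends)) next
        # cluster end positions into loci; alignments of one locus end within
        # a band of each other
        grp <- cumsum(c(TRUE, diff(hit_ends) > band + 1L))
        for (g in split(hit_ends, grp)) {
          best_end <- g[which.min(ends[g])]
          res <- .window_at_end(query, txseq[[tx]], best_end, band)
          hits[[length(hits) + 1L]] <- data.frame(
            probe_id = pid, transcript_id = tx,
            mismatches = as.integer(res$dist),
            target_start = res$start, target_end = res$end,
            strand = qstrand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) return(.empty_hits())
  out <- do.call(rbind, hits)
  # best hit per (probe, transcript, strand, locus): merge hits whose target
  # spans overlap, keep the lowest-mismatch one
  out <- out[order(out$probe_id, out$transcript_id, out$strand,
                   out$mismatches), , drop = FALSE]
  sel <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!sel[i]) next
    j <- which(sel & seq_len(nrow(out)) > i &
                 out$probe_id == out$probe_id[i] &
                 out$transcript_id == out$transcript_id[i] &
                 out$strand == out$strand[i] &
                 out$target_start <= out$target_end[i] &
                 out$target_end >= out$target_start[i])
    sel[j] <- FALSE
  }
  out <- out[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_hits <- function() {
  data.frame(probe_id = character(), transcript_id = character(),
             mismatches = integer(), target_start = integer(),
             target_end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

# candidate loci for a query via shared k-mers. Each shared k-mer implies a
# window start (seed position minus query offset); implied starts on the same
# transcript are clustered when consecutive starts are within `band`, and the
# caller scans window starts over [lo - band, hi + band] per cluster, so no
# within-budget alignment escapes the scan (pigeonhole: <= band mismatches in
# a query of length >= k + band leaves an exact k-mer, whose implied start is
# within band of the true window start).
.seed_loci <- function(query, idx, band) {
  k <- idx$k
  nq <- nchar(query)
  none <- data.frame(tx = character(), lo = integer(), hi = integer(),
                     stringsAsFactors = FALSE)
  if (nq < k) return(none)
  kmers <- substring(query, 1:(nq - k + 1L), k:nq)
  posts <- list()
  for (i in seq_along(kmers)) {
    p <- idx$index[[kmers[i]]]
    if (is.null(p)) next
    p <- p[p$strand == "+", , drop = FALSE]   # query strand handled by caller
    if (!nrow(p)) next
    posts[[length(posts) + 1L]] <- data.frame(tx = p$tx, lo = p$pos - (i - 1L),
                                              stringsAsFactors = FALSE)
  }
  if (!length(posts)) return(none)
  loci <- unique(do.call(rbind, posts))
  loci <- loci[order(loci$tx, loci$lo), , drop = FALSE]
  newgrp <- c(TRUE, diff(loci$lo) > band | loci$tx[-1] != loci$tx[-nrow(loci)])
  grp <- cumsum(newgrp)
  data.frame(tx = tapply(loci$tx, grp, `[`, 1L),
             lo = as.integer(tapply(loci$lo, grp, min)),
             hi = as.integer(tapply(loci$lo, grp, max)),
             stringsAsFactors = FALSE)
}

#' Write off-target hits to TSV
#' @param hits [screen_offtargets()] output.
#' @param path Output path.
#' @param comments Optional comment header lines.
#' @return `path`, invisibly.
#' @export
write_offtarget_hits <- function(hits, path, comments = character()) {
  write_tsv(hits, path, comments = comments)
}
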