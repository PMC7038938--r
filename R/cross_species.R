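#' Global pairwise alignment of two rRNA sequences
#'
#' End-to-end (Needleman-Wunsch) alignment with affine gap costs: match +1,
#' mismatch -1, gap open -4, gap extend -1 (a gap of length g costs 4 + g).
#' The alignment backend is Biostrings; this wrapper adds per-column source
#' position maps used for mapping probe tiles through the alignment.
#'
#' @param a,b [seq_record]s (or plain sequence strings), both non-empty.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (defaults
#'   above; `gap_open`/`gap_extend` given as positive costs).
#' @return An object of class `pairwise_alignment` with fields `a_aligned`,
#'   `b_aligned` (equal-length gapped strings), `col_to_a`, `col_to_b`
#'   (1-based source position per column, `NA` at gaps), and `score`.
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1,
                       gap_open = 4, gap_extend = 1) {
  sa <- if (inherits(a, "seq_record")) a$seq else gsub("U", "T", toupper(a), fixed = TRUE)
  sb <- if (inherits(b, "seq_record")) b$seq else gsub("U", "T", toupper(b), fixed = TRUE)
  .check_alphabet(sa); .check_alphabet(sb)
  if (!nchar(sa) || !nchar(sb)) stop("align_pair: empty sequence")
  submat <- .iupac_submat(match, mismatch)
  pa <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
                                      substitutionMatrix = submat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  a_aln <- as.character(Biostrings::alignedPattern(pa))
  b_aln <- as.character(Biostrings::alignedSubject(pa))
  ac <- strsplit(a_aln, "")[[1]]
  bc <- strsplit(b_aln, "")[[1]]
  col_to_a <- ifelse(ac == "-", NA_integer_, cumsum(ac != "-"))
  col_to_b <- ifelse(bc == "-", NA_integer_, cumsum(bc != "-"))
  structure(list(a_aligned = a_aln, b_aligned = b_aln,
                 col_to_a = as.integer(col_to_a),
                 col_to_b = as.integer(col_to_b),
                 score = Biostrings::score(pa)),
            class = "pairwise_alignment")
}

# literal-identity substitution matrix over the IUPAC alphabet
.iupac_submat <- function(match, mismatch) {
  n <- length(IUPAC_CHARS)
  m <- matrix(mismatch, n, n, dimnames = list(IUPAC_CHARS, IUPAC_CHARS))
  diag(m) <- match
  m
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %d columns, score %.1f, %.2f%% mismatch\n",
              nchar(x$a_aligned), x$score, overall_mismatch_pct(x)))
  invisible(x)
}

#' Overall mismatch percentage of an alignment
#'
#' 100 x (columns where the two characters differ, gap columns counted as
#' mismatches) / alignment length. This is the probe-to-target similarity
#' statistic computed on whole 16S or 23S alignments.
#'
#' @param aln A [align_pair()] result.
#' @return Percent in `[0, 100]`.
#' @export
overall_mismatch_pct <- function(aln) {
  ac <- strsplit(aln$a_aligned, "")[[1]]
  bc <- strsplit(aln$b_aligned, "")[[1]]
  100 * sum(ac != bc) / length(ac)
}

#' Per-probe tile mismatch percentages
#'
#' Maps each probe's tile on sequence `a` through the alignment to a
#' contiguous block of columns (gap columns are assigned to the tile holding
#' the nearest preceding non-gap `a` position, i.e. to the 5' tile at
#' boundaries) and reports 100 x mismatch-or-gap columns / block length.
#'
#' @param aln A [align_pair()] result where sequence `a` is the probe-source
#'   rRNA.
#' @param library A [probe_library] designed on sequence `a`; only probes of
#'   one gene should be passed when `a` is that gene.
#' @param gene Optional gene filter (`"16S"` or `"23S"`).
#' @return Data frame with columns `probe_id`, `tile_mismatch_pct`.
#' @export
per_probe_mismatch <- function(aln, library, gene = NULL) {
  probes <- library$probes
  if (!is.null(gene)) probes <- probes[probes$gene == gene, , drop = FALSE]
  ac <- strsplit(aln$a_aligned, "")[[1]]
  bc <- strsplit(aln$b_aligned, "")[[1]]
  mism <- ac != bc
  # a-position owning each column: gap-in-a columns inherit the last non-gap
  # a position to their left (5' assignment); leading gaps go to position 1.
  owner <- aln$col_to_a
  last <- 0L
  for (i in seq_along(owner)) {
    if (is.na(owner[i])) owner[i] <- max(last, 1L) else last <- owner[i]
  }
  la <- sum(!is.na(aln$col_to_a))
  out <- lapply(seq_len(nrow(probes)), function(i) {
    s <- probes$tile_start[i] + 1L   # 1-based inclusive on a
    e <- probes$tile_end[i]
    if (s < 1L || e > la)
      stop("consistency error: probe ", probes$probe_id[i],
           " outside aligned sequence (", la, " nt)")
    block <- owner >= s & owner <= e
    data.frame(probe_id = probes$probe_id[i],
               tile_mismatch_pct = 100 * sum(mism[block]) / sum(block),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gene-level similarity report
#'
#' @param gene `"16S"` or `"23S"`.
#' @param aln Alignment of the probe-source gene (as `a`) to the target gene.
#' @param library The probe library designed on the source.
#' @return A list of class `similarity_report` with `gene`,
#'   `overall_mismatch_pct` and `per_probe`.
#' @export
similarity_report <- function(gene, aln, library) {
  structure(list(gene = gene,
                 overall_mismatch_pct = overall_mismatch_pct(aln),
                 per_probe = per_probe_mismatch(aln, library, gene = gene)),
            class = "similarity_report")
}

#' Predict cross-species applicability of a probe library
#'
#' A library designed for one species is predicted to deplete a related
#' species' rRNA when the average of the 16S and 23S overall mismatch
#' percentages is below `overall_threshold` (default 10%). The fraction of
#' probes below `local_threshold` (default 25%) tile mismatch — the "locally
#' effective" probes — is reported alongside.
#'
#' @param report_16S,report_23S [similarity_report]s for the two genes.
#' @param overall_threshold Percent; default 10.
#' @param local_threshold Percent; default 25.
#' @return List of class `applicability` with `applicable` (logical),
#'   `mean_mismatch_pct`, `locally_effective_fraction`, `rationale`.
#' @export
predict_applicability <- function(report_16S, report_23S,
                                  overall_threshold = 10,
                                  local_threshold = 25) {
  stopifnot(inherits(report_16S, "similarity_report"),
            inherits(report_23S, "similarity_report"))
  mean_mm <- mean(c(report_16S$overall_mismatch_pct,
                    report_23S$overall_mismatch_pct))
  per_probe <- rbind(report_16S$per_probe, report_23S$per_probe)
  frac_local <- mean(per_probe$tile_mismatch_pct < local_threshold)
  applicable <- mean_mm < overall_threshold
  structure(list(
    applicable = applicable,
    mean_mismatch_pct = mean_mm,
    locally_effective_fraction = frac_local,
    rationale = sprintf(
      "mean 16S/23S mismatch %.2f%% %s %.0f%% threshold; %.0f%% of probes < %.0f%% tile mismatch",
      mean_mm, if (applicable) "<" else ">=", overall_threshold,
      100 * frac_local, local_threshold)),
    class = "applicability")
}

#' @export
print.applicability <- function(x, ...) {
  cat(if (x$applicable) "APPLICABLE: " else "NOT APPLICABLE: ", x$rationale, "\n",
      sep = "")
  invisible(x)
}

#' Evaluate a probe library against a target species
#'
#' Convenience wrapper: aligns source and target 16S and 23S, builds per-gene
#' [similarity_report]s and the [predict_applicability()] verdict.
#'
#' @param library [probe_library] designed on the source rRNAs.
#' @param source_rrnas,target_rrnas Lists of two [seq_record]s each (16S/23S
#'   tagged in id or description).
#' @inheritParams predict_applicability
#' @return List with `reports` (per gene) and `verdict`.
#' @export
evaluate_library <- function(library, source_rrnas, target_rrnas,
                             overall_threshold = 10, local_threshold = 25) {
  pick <- function(recs, gene) {
    hit <- vapply(recs, function(r)
      grepl(gene, paste(r$id, r$desc), ignore.case = TRUE), logical(1))
    if (sum(hit) != 1L) stop("need exactly one ", gene, "-tagged record")
    recs[[which(hit)]]
  }
  reports <- lapply(c("16S", "23S"), function(gene) {
    aln <- align_pair(pick(source_rrnas, gene), pick(target_rrnas, gene))
    similarity_report(gene, aln, library)
  })
  names(reports) <- c("16S", "23S")
  verdict <- predict_applicability(reports[["16S"]], reports[["23S"]],
                                   overall_threshold, local_threshold)
  list(reports = reports, verdict = verdict)
}
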