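#' Tile a sequence into equal-as-possible segments
#'
#' Splits the interval `[0, L)` into `k = ceiling(L / target_len)` abutting
#' tiles whose lengths differ by at most one base; longer tiles are placed
#' first (5' end). This is the tiling used to turn an rRNA gene into a set of
#' ~50 nt antisense oligo probes covering its entire length.
#'
#' @param rrna A [seq_record] (or plain sequence string).
#' @param target_len Target tile length in nt (default 50, minimum 20).
#' @return A data frame with 0-based half-open columns `start`, `end`.
#' @export
tile_sequence <- function(rrna, target_len = 50L) {
  seq <- if (inherits(rrna, "seq_record")) rrna$seq else rrna
  L <- nchar(seq)
  target_len <- as.integer(target_len)
  if (target_len < 20L) stop("design error: target_len must be >= 20")
  if (L < target_len)
    stop("design error: sequence (", L, " nt) shorter than target_len (",
         target_len, ")")
  k <- ceiling(L / target_len)
  base_len <- L %/% k
  n_long <- L %% k              # this many tiles get base_len + 1, placed 5'-first
  lens <- c(rep(base_len + 1L, n_long), rep(base_len, k - n_long))
  end <- cumsum(lens)
  data.frame(start = c(0L, end[-k]), end = end)
}

#' Probe library constructor
#'
#' @param organism Organism tag.
#' @param probes Data frame with columns `probe_id`, `gene`, `tile_start`,
#'   `tile_end` (0-based half-open on the rRNA sense strand), `seq` (antisense
#'   DNA).
#' @param provenance `"oligo"` or `"amplicon"`.
#' @param pool_fractions Per-probe molar fractions; default equimolar.
#' @return An object of class `probe_library`.
#' @export
probe_library <- function(organism, probes, provenance = c("oligo", "amplicon"),
                          pool_fractions = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "gene", "tile_start", "tile_end", "seq") %in%
                  colnames(probes)))
  if (is.null(pool_fractions))
    pool_fractions <- rep(1 / nrow(probes), nrow(probes))
  if (abs(sum(pool_fractions) - 1) > 1e-9)
    stop("pool_fractions must sum to 1")
  structure(list(organism = organism, probes = probes,
                 provenance = provenance, pool_fractions = pool_fractions),
            class = "probe_library")
}

#' @export
print.probe_library <- function(x, ...) {
  cat(sprintf("<probe_library> %s: %d %s probes (%s)\n", x$organism,
              nrow(x$probes), x$provenance,
              paste(sprintf("%s: %d", unique(x$probes$gene),
                            table(x$probes$gene)[unique(x$probes$gene)]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.probe_library <- function(x) nrow(x$probes)

#' Design a tiled antisense oligo probe library
#'
#' Tiles one 16S and one 23S rRNA into ~`target_len` nt segments and emits the
#' reverse complement of every tile as a ssDNA probe, ordered 16S then 23S and
#' 5' to 3' along each gene, pooled equimolarly. Gene assignment is taken from
#' record ids/descriptions containing "16S" or "23S".
#'
#' @param rrnas List of two [seq_record]s, one tagged 16S and one 23S.
#' @param target_len Target probe length (default 50 nt).
#' @param organism Organism tag used in probe names (default: 16S record id).
#' @return A [probe_library] with provenance `"oligo"`.
#' @export
design_oligo_library <- function(rrnas, target_len = 50L, organism = NULL) {
  tags <- vapply(rrnas, function(r) {
    hit <- c(grepl("16S", paste(r$id, r$desc), ignore.case = TRUE),
             grepl("23S", paste(r$id, r$desc), ignore.case = TRUE))
    if (sum(hit) != 1L) NA_character_ else c("16S", "23S")[hit]
  }, character(1))
  if (anyNA(tags) || !setequal(tags, c("16S", "23S")))
    stop("design error: need exactly one 16S-tagged and one 23S-tagged record")
  rrnas <- rrnas[order(match(tags, c("16S", "23S")))]
  if (is.null(organism))
    organism <- sub("_?(16S|23S).*$", "", rrnas[[1]]$id, ignore.case = TRUE)
  if (!nzchar(organism)) organism <- "org"
  probes <- do.call(rbind, lapply(seq_along(rrnas), function(g) {
    gene <- c("16S", "23S")[g]
    r <- rrnas[[g]]
    tiles <- tile_sequence(r, target_len)
    data.frame(
      probe_id = sprintf("%s_%s_%02d_%d-%d", organism, gene,
                         seq_len(nrow(tiles)), tiles$start + 1L, tiles$end),
      gene = gene,
      tile_start = tiles$start, tile_end = tiles$end,
      seq = vapply(seq_len(nrow(tiles)), function(i)
        reverse_complement(substr(r$seq, tiles$start[i] + 1L, tiles$end[i])),
        character(1)),
      stringsAsFactors = FALSE)
  }))
  probe_library(organism, probes, provenance = "oligo")
}

#' Primer pair for amplicon probe generation
#'
#' Universal rRNA primers; the forward primer is 5'-phosphorylated so lambda
#' exonuclease digestion of the amplicon leaves the antisense strand as probe.
#'
#' @param name `"16S"` or `"23S"`.
#' @param fwd,rev Primer sequences 5' to 3' (IUPAC codes allowed); `rev` binds
#'   the reverse-complement strand.
#' @param max_primer_mismatches Internal mismatches tolerated per primer
#'   (default 2); the 3'-terminal base must always match exactly.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(name, fwd, rev, max_primer_mismatches = 2L) {
  stopifnot(name %in% c("16S", "23S"))
  fwd <- toupper(fwd); rev <- toupper(rev)
  .check_alphabet(fwd); .check_alphabet(rev)
  if (nchar(fwd) < 10L || nchar(rev) < 10L)
    stop("primers must be at least 10 nt")
  structure(list(name = name, fwd = fwd, rev = rev,
                 phosphorylated = "fwd",
                 max_primer_mismatches = as.integer(max_primer_mismatches)),
            class = "primer_pair")
}

# IUPAC compatibility: does primer base p cover template base t?
.iupac_sets <- local({
  m <- list(A = "A", C = "C", G = "G", T = "T",
            R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
            K = c("G", "T"), M = c("A", "C"),
            B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
            V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  m
})

iupac_match <- function(primer_base, template_base) {
  template_base %in% .iupac_sets[[primer_base]]
}

# number of mismatching positions of primer placed at template[start..], or NA
.primer_mismatches <- function(primer, template_chars, start) {
  n <- nchar(primer)
  if (start < 1L || start + n - 1L > length(template_chars)) return(NA_integer_)
  pb <- strsplit(primer, "")[[1]]
  tb <- template_chars[start:(start + n - 1L)]
  mm <- sum(!mapply(iupac_match, pb, tb))
  if (!iupac_match(pb[n], tb[n])) return(NA_integer_)  # 3'-terminal must match
  mm
}

#' In-silico PCR of an rRNA amplicon
#'
#' Scans the template for the leftmost forward-primer site and its nearest
#' downstream reverse-primer site (the reverse primer binds the bottom
#' strand). IUPAC degeneracy in primers matches any compatible template base;
#' up to `max_primer_mismatches` internal mismatches are tolerated but the
#' 3'-terminal base of each primer must match exactly. The returned record
#' represents the double-stranded amplicon and is tagged with which strand is
#' 5'-phosphorylated (the forward-synthesized sense strand).
#'
#' @param template A [seq_record] (genomic region containing the gene).
#' @param primers A [primer_pair].
#' @return A `seq_record` for the sense strand of the amplicon with attributes
#'   `phosphorylated_strand = "sense"` and `amplicon_start` (1-based on the
#'   template).
#' @export
in_silico_pcr <- function(template, primers) {
  tc <- strsplit(template$seq, "")[[1]]
  L <- length(tc)
  maxmm <- primers$max_primer_mismatches
  nf <- nchar(primers$fwd)
  fwd_start <- NA_integer_
  for (s in seq_len(L - nf + 1L)) {
    mm <- .primer_mismatches(primers$fwd, tc, s)
    if (!is.na(mm) && mm <= maxmm) { fwd_start <- s; break }
  }
  if (is.na(fwd_start))
    stop("amplification failure: no site for forward primer ", primers$name)
  # reverse primer anneals to the bottom strand: its site on the top strand is
  # reverse_complement(rev); the primer 3' end corresponds to the site's start.
  rc_rev <- reverse_complement(primers$rev)
  nr <- nchar(rc_rev)
  rc_chars <- strsplit(rc_rev, "")[[1]]
  rev_end <- NA_integer_
  rev_starts <- if (L - nr + 1L >= fwd_start) seq(fwd_start, L - nr + 1L) else integer()
  for (s in rev_starts) {
    ok <- TRUE
    mm <- 0L
    for (j in seq_len(nr)) {
      # primer base j (3'->5' on top strand after revcomp); 3'-terminal base of
      # the rev primer maps to position s (start of the top-strand site)
      pb <- rc_chars[j]
      if (!iupac_match(pb, tc[s + j - 1L])) {
        if (j == 1L) { ok <- FALSE; break }   # 3' terminal of rev primer
        mm <- mm + 1L
        if (mm > maxmm) { ok <- FALSE; break }
      }
    }
    if (ok && s >= fwd_start) { rev_end <- s + nr - 1L; break }
  }
  if (is.na(rev_end))
    stop("amplification failure: no site for reverse primer ", primers$name)
  amp <- substr(template$seq, fwd_start, rev_end)
  out <- seq_record(paste0(template$id, "_", primers$name, "_amplicon"), amp,
                    desc = sprintf("in-silico PCR %d-%d of %s", fwd_start,
                                   rev_end, template$id))
  attr(out, "phosphorylated_strand") <- "sense"
  attr(out, "amplicon_start") <- fwd_start
  out
}

#' Lambda exonuclease strand selection
#'
#' Digests the 5'-phosphorylated strand of a double-stranded amplicon, leaving
#' the complementary strand as a single-stranded DNA probe. With a
#' phosphorylated forward primer the surviving strand is antisense to the rRNA.
#'
#' @param amplicon Output of [in_silico_pcr()] (must carry exactly one
#'   `phosphorylated_strand` tag).
#' @return A `seq_record` holding the ssDNA probe (antisense strand).
#' @export
lambda_digest <- function(amplicon) {
  ph <- attr(amplicon, "phosphorylated_strand")
  if (is.null(ph) || !ph %in% c("sense", "antisense"))
    stop("state error: amplicon must have exactly one phosphorylated strand")
  probe_seq <- if (ph == "sense") reverse_complement(amplicon$seq) else amplicon$seq
  seq_record(sub("_amplicon$", "_probe", amplicon$id), probe_seq,
             desc = "ssDNA probe (lambda exonuclease digest)")
}

#' Build an amplicon probe library
#'
#' Runs [in_silico_pcr()] and [lambda_digest()] for the 16S and 23S primer
#' pairs and pools the two full-length ssDNA probes equimolarly.
#'
#' @param template_16S,template_23S [seq_record]s containing each gene (with
#'   any flanking sequence the primers fall in).
#' @param primers_16S,primers_23S [primer_pair]s.
#' @param organism Organism tag.
#' @return A [probe_library] with provenance `"amplicon"` and 2 probes. Tile
#'   coordinates are the amplicon span on each template (0-based half-open).
#' @export
design_amplicon_library <- function(template_16S, template_23S,
                                    primers_16S, primers_23S,
                                    organism = "org") {
  mk <- function(template, primers, gene) {
    amp <- in_silico_pcr(template, primers)
    probe <- lambda_digest(amp)
    s0 <- attr(amp, "amplicon_start") - 1L
    data.frame(probe_id = sprintf("%s_%s_amplicon", organism, gene),
               gene = gene, tile_start = s0, tile_end = s0 + nchar(amp$seq),
               seq = probe$seq, stringsAsFactors = FALSE)
  }
  probes <- rbind(mk(template_16S, primers_16S, "16S"),
                  mk(template_23S, primers_23S, "23S"))
  probe_library(organism, probes, provenance = "amplicon")
}

#' Write a probe sheet TSV
#'
#' Columns: `probe_id`, `organism`, `gene`, `start`, `end`, `length`,
#' `sequence`, with 1-based inclusive coordinates on the rRNA sense strand.
#'
#' @param library A [probe_library].
#' @param path Output path.
#' @param comments Optional comment header lines.
#' @return `path`, invisibly.
#' @export
write_probe_sheet <- function(library, path, comments = character()) {
  p <- library$probes
  df <- data.frame(probe_id = p$probe_id, organism = library$organism,
                   gene = p$gene, start = p$tile_start + 1L, end = p$tile_end,
                   length = p$tile_end - p$tile_start, sequence = p$seq,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, comments = c(
    paste0("provenance: ", library$provenance), comments))
}

#' Read a probe sheet TSV written by [write_probe_sheet()]
#'
#' @param path Probe sheet path.
#' @return A [probe_library].
#' @export
read_probe_sheet <- function(path) {
  first <- readLines(path, n = 1L)
  provenance <- if (grepl("provenance: amplicon", first)) "amplicon" else "oligo"
  df <- read_tsv(path)
  need <- c("probe_id", "organism", "gene", "start", "end", "sequence")
  if (!all(need %in% colnames(df)))
    stop("probe sheet format error: missing column(s) ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  probe_library(df$organism[1],
                data.frame(probe_id = df$probe_id, gene = df$gene,
                           tile_start = df$start - 1L, tile_end = df$end,
                           seq = toupper(df$sequence), stringsAsFactors = FALSE),
                provenance = provenance)
}
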