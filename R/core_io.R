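#' Sequence record
#'
#' A lightweight container for one nucleotide sequence: an identifier (first
#' whitespace-delimited token of a FASTA header), an optional free-text
#' description, the sequence itself (uppercase, U canonicalized to T), and a
#' flag recording whether the original input used the RNA alphabet.
#'
#' @param id Identifier token (no whitespace).
#' @param seq Nucleotide string over the IUPAC alphabet (A, C, G, T, U, N and
#'   degeneracy codes). Stored uppercase with U replaced by T.
#' @param desc Free-text description (may be empty).
#' @param rna Logical; `TRUE` when the original sequence contained U.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, seq, desc = "", rna = FALSE) {
  if (!is.character(id) || length(id) != 1L || grepl("[[:space:]]", id) || !nzchar(id))
    stop("seq_record: 'id' must be a single non-empty token without whitespace")
  seq <- toupper(seq)
  if (grepl("U", seq, fixed = TRUE)) {
    rna <- TRUE
    seq <- gsub("U", "T", seq, fixed = TRUE)
  }
  .check_alphabet(seq)
  if (nchar(seq) < 1L) stop("seq_record: empty sequence for '", id, "'")
  structure(list(id = id, desc = desc, seq = seq, rna = rna),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  s <- x$seq
  shown <- if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  cat(sprintf("<seq_record> %s (%d nt%s)\n  %s\n",
              x$id, nchar(s), if (x$rna) ", RNA input" else "", shown))
  invisible(x)
}

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

.check_alphabet <- function(seq) {
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), IUPAC_CHARS)
  if (length(bad))
    stop("non-IUPAC character(s) in sequence: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Read a FASTA file
#'
#' Parses a (multi-)FASTA file into a list of [seq_record] objects. Sequences
#' are uppercased and U is canonicalized to T; records whose input contained U
#' carry `rna = TRUE` so [write_fasta()] can restore the original alphabet.
#'
#' @param path Path to a FASTA file.
#' @return List of `seq_record`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA format error in ", path, ": no records")
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  if (any(!nzchar(ids)))
    stop("FASTA format error in ", path, ": empty header at record ",
         which(!nzchar(ids))[1])
  if (anyDuplicated(ids))
    stop("FASTA format error in ", path, ": duplicate id '",
         ids[duplicated(ids)][1], "'")
  descs <- ifelse(grepl("[[:space:]]", headers),
                  sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  seqs <- as.character(set)
  empty <- which(nchar(seqs) == 0L)
  if (length(empty))
    stop("FASTA format error in ", path, ": empty sequence for '",
         ids[empty[1]], "'")
  mapply(function(i, s, d) seq_record(i, s, d), ids, seqs, descs,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write FASTA
#'
#' Writes a list of [seq_record] to FASTA, wrapped at 80 columns. Records
#' flagged as RNA input are written back in the RNA alphabet (T restored to U).
#'
#' @param records List of `seq_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in records) {
    s <- r$seq
    if (isTRUE(r$rna)) s <- gsub("T", "U", s, fixed = TRUE)
    header <- if (nzchar(r$desc)) paste(r$id, r$desc) else r$id
    writeLines(paste0(">", header), con)
    starts <- seq(1L, nchar(s), by = 80L)
    writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement with IUPAC support
#'
#' @param seq Nucleotide string (IUPAC codes allowed; U treated as T).
#' @return The reverse complement as a DNA string.
#' @export
reverse_complement <- function(seq) {
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  .check_alphabet(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read CDS features from GFF3
#'
#' Consumes only rows of type `CDS`; coordinates are kept 1-based inclusive as
#' in GFF3. The feature identifier is taken from the `ID=` attribute (falling
#' back to `locus_tag=`), and must be unique within the file.
#'
#' @param path Path to a GFF3 file.
#' @return A data frame with columns `seq_id`, `start`, `end`, `strand`,
#'   `feature_id` (one row per CDS; zero rows when the file has no CDS).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      strand = character(), feature_id = character(),
                      stringsAsFactors = FALSE)
  if (!length(body)) return(empty)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop("GFF3 format error in ", path, ": line with ", min(nf),
         " columns (9 required)")
  type <- vapply(fields, `[[`, "", 3L)
  keep <- which(type == "CDS")
  if (!length(keep)) return(empty)
  fields <- fields[keep]
  start <- as.integer(vapply(fields, `[[`, "", 4L))
  end <- as.integer(vapply(fields, `[[`, "", 5L))
  if (anyNA(start) || anyNA(end))
    stop("GFF3 format error in ", path, ": non-numeric CDS coordinates")
  bad <- which(end < start | start < 1L)
  if (length(bad))
    stop("GFF3 format error in ", path, ": end < start (or start < 1) at CDS row ",
         bad[1])
  attrs <- vapply(fields, `[[`, "", 9L)
  feature_id <- .gff_attr(attrs, "ID")
  fallback <- is.na(feature_id)
  if (any(fallback)) feature_id[fallback] <- .gff_attr(attrs[fallback], "locus_tag")
  if (anyNA(feature_id))
    stop("GFF3 format error in ", path, ": CDS without ID or locus_tag attribute")
  if (anyDuplicated(feature_id))
    stop("GFF3 format error in ", path, ": duplicate CDS id '",
         feature_id[duplicated(feature_id)][1], "'")
  data.frame(seq_id = vapply(fields, `[[`, "", 1L),
             start = start, end = end,
             strand = vapply(fields, `[[`, "", 7L),
             feature_id = feature_id,
             stringsAsFactors = FALSE)
}

.gff_attr <- function(attrs, key) {
  pat <- paste0("(^|;)", key, "=([^;]*)")
  m <- regexpr(pat, attrs)
  out <- rep(NA_character_, length(attrs))
  hit <- m > 0
  out[hit] <- sub(pat, "\\2", regmatches(attrs, m))
  out
}

#' Read primary alignments from a text SAM file
#'
#' Returns one record per primary alignment line. The unmapped flag comes from
#' FLAG bit 0x4; a read is marked `multi_mapped` when any secondary alignment
#' (FLAG bit 0x100) exists for it or when an alignment-count tag (`NH:i` or
#' `X0:i`) exceeds 1. Reference length consumed on the reference is computed
#' from the CIGAR (M, =, X, D and N advance the reference).
#'
#' @param path Path to a SAM text file with `@SQ` header lines.
#' @return A data frame with columns `read_id`, `ref_id` (`NA` when unmapped),
#'   `pos`, `aln_len`, `multi_mapped`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (!length(sq)) stop("SAM format error in ", path, ": no @SQ header lines")
  refs <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  if (!length(body))
    return(data.frame(read_id = character(), ref_id = character(),
                      pos = integer(), aln_len = integer(),
                      multi_mapped = logical(), stringsAsFactors = FALSE))
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L))
    stop("SAM format error in ", path, ": alignment line with < 11 fields")
  read_id <- vapply(fields, `[[`, "", 1L)
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  rname <- vapply(fields, `[[`, "", 3L)
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  cigar <- vapply(fields, `[[`, "", 6L)
  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L
  bad_ref <- !unmapped & !(rname %in% refs)
  if (any(bad_ref))
    stop("SAM consistency error in ", path, ": reference '",
         rname[bad_ref][1], "' absent from @SQ headers")
  nh <- vapply(fields, function(f) {
    tags <- f[-(1:11)]
    hit <- grep("^(NH|X0):i:", tags, value = TRUE)
    if (length(hit)) as.integer(sub("^..:i:", "", hit[1])) else NA_integer_
  }, integer(1))
  multi_ids <- unique(c(read_id[secondary], read_id[!is.na(nh) & nh > 1L]))
  primary <- !secondary
  data.frame(
    read_id = read_id[primary],
    ref_id = ifelse(unmapped[primary], NA_character_, rname[primary]),
    pos = ifelse(unmapped[primary], NA_integer_, pos[primary]),
    aln_len = ifelse(unmapped[primary], NA_integer_,
                     vapply(cigar[primary], cigar_ref_length, integer(1),
                            USE.NAMES = FALSE)),
    multi_mapped = read_id[primary] %in% multi_ids,
    stringsAsFactors = FALSE)
}

#' Reference-consumed length of a CIGAR string
#'
#' @param cigar CIGAR string; `*` yields `NA`.
#' @return Integer number of reference bases spanned.
#' @export
cigar_ref_length <- function(cigar) {
  if (cigar == "*") return(NA_integer_)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  sum(len[op %in% c("M", "=", "X", "D", "N")])
}

# internal: write a TSV with optional comment header lines
write_tsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    rows <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) formatC(col, format = "fg", digits = 15)
      else as.character(col)
    }), sep = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
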