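# shared fixture builders (all synthetic, generated in code)

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

toy_rrnas <- function(seed = 1, len16 = 150, len23 = 300) {
  set.seed(seed)
  list(seq_record("org_16S", random_dna(len16)),
       seq_record("org_23S", random_dna(len23)))
}

# minimal SAM: one @SQ per ref, simple alignment lines
sam_lines <- function(aln, refs) {
  c(sprintf("@SQ\tSN:%s\tLN:%d", names(refs), unname(refs)),
    vapply(aln, identity, ""))
}

sam_aln_line <- function(read_id, flag, ref, pos, cigar, seq = "ACGT") {
  sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
          read_id, flag, ref, pos, cigar, seq)
}
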