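# independent oracles, plain R, kept free of the code paths they check

# global affine-gap alignment score by direct dynamic programming over the
# three gap states (a gap of length g costs open + g * ext)
nw_affine_oracle_score <- function(a, b, match = 1, mismatch = -1,
                                   open = 4, ext = 1) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # a[i] aligned to b[j]
  X <- matrix(NEG, n + 1, m + 1)   # a[i] aligned to gap
  Y <- matrix(NEG, n + 1, m + 1)   # gap aligned to b[j]
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (ac[i] == bc[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# best end-to-end probe placement on a transcript: minimum substitutions +
# gap columns over every window. Computed as a probe-global / subject-local
# alignment under unit edit costs (match 0, mismatch -1, gap column -1), so
# -score is the semi-global Levenshtein distance. Exhaustive over the whole
# transcript; independent of the seeded search under test.
semi_global_distance_oracle <- function(probe, txseq, band = 8L) {
  letters <- c("A", "C", "G", "T", "N")
  submat <- matrix(-1, 5, 5, dimnames = list(letters, letters))
  diag(submat) <- 0
  pa <- Biostrings::pairwiseAlignment(probe, txseq, type = "global-local",
                                      substitutionMatrix = submat,
                                      gapOpening = 0, gapExtension = 1)
  -Biostrings::score(pa)
}

# slow reference for the oracle itself: Levenshtein over every window
semi_global_distance_bruteforce <- function(probe, txseq, band = 8L) {
  np <- nchar(probe); L <- nchar(txseq)
  best <- Inf
  for (len in max(1L, np - band):(np + band)) {
    if (len > L) next
    wins <- substring(txseq, 1:(L - len + 1L), len:L)
    best <- min(best, min(utils::adist(probe, wins)))
  }
  best
}

# enumerate every primer placement to find the amplicon a PCR would make
pcr_oracle <- function(template, primers) {
  tc <- strsplit(template, "")[[1]]
  place <- function(primer) {
    np <- nchar(primer)
    pb <- strsplit(primer, "")[[1]]
    ok <- integer(0)
    for (s in seq_len(length(tc) - np + 1L)) {
      tb <- tc[s:(s + np - 1L)]
      mm <- sum(!mapply(riboprobe:::iupac_match, pb, tb))
      if (riboprobe:::iupac_match(pb[np], tb[np]) &&
          mm <= primers$max_primer_mismatches)
        ok <- c(ok, s)
    }
    ok
  }
  fwd_sites <- place(primers$fwd)
  if (!length(fwd_sites)) return(NULL)
  f <- min(fwd_sites)
  rc <- reverse_complement(primers$rev)
  # on the top strand the rev site reads revcomp(rev); its 3'-terminal base is
  # the first position of the site
  np <- nchar(rc)
  pb <- strsplit(rc, "")[[1]]
  rev_sites <- integer(0)
  for (s in seq_len(length(tc) - np + 1L)) {
    tb <- tc[s:(s + np - 1L)]
    if (!riboprobe:::iupac_match(pb[1], tb[1])) next
    mm <- sum(!mapply(riboprobe:::iupac_match, pb, tb))
    if (mm <= primers$max_primer_mismatches) rev_sites <- c(rev_sites, s)
  }
  rev_sites <- rev_sites[rev_sites >= f]
  if (!length(rev_sites)) return(NULL)
  r <- min(rev_sites)
  list(start = f, end = r + np - 1L)
}

# rank-then-Pearson Spearman
spearman_oracle <- function(x, y) stats::cor(rank(x), rank(y))
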