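Package: riboprobe
Title: Design and Assessment of RNase H Probe Libraries for Bacterial rRNA Depletion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for ribonuclease H based removal of bacterial ribosomal RNA
    from RNA-seq libraries. Designs tiled antisense ssDNA oligo probe libraries
    against 16S and 23S rRNA sequences, simulates amplicon-derived probes by
    in-silico PCR and lambda exonuclease strand selection, predicts whether a
    probe library carries over to related species from alignment mismatch
    fractions, screens probes for off-target transcripts, simulates
    probe-directed depletion of fragmented total-RNA pools with ground-truth
    labels, and computes depletion-performance and transcriptome-consistency
    statistics (rRNA read fraction, fold enrichment of non-rRNA reads, TPM,
    correlations of log-transformed expression, Q-Q quantile pairs,
    Mann-Whitney effect sizes, and classical MDS ordination of samples).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Rsamtools
Config/testthat/edition: 3
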