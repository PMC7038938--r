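---
title: "Probe-based rRNA depletion: models and methods in riboprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-based rRNA depletion: models and methods in riboprobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboprobe)
```

## The problem

In bacteria the 16S and 23S ribosomal RNAs make up more than 90% of total
RNA. RNA-seq of a bacterial isolate therefore wastes most of its reads on
rRNA unless the rRNA is physically removed during library preparation.
One removal chemistry that works on *fragmented* RNA (as produced by pooled,
barcoded protocols such as RNAtag-seq) is RNase H digestion: single-stranded
DNA probes antisense to the rRNA are hybridized to the RNA pool, RNase H
cleaves the RNA strand of every RNA:DNA duplex, and the probes are then
removed with DNase I. The method needs a probe set per species, which is
where this package comes in. It covers the computational side of that
workflow:

* designing tiled antisense oligo probe libraries from 16S/23S sequences,
  and emulating amplicon-derived probes (in-silico PCR plus lambda
  exonuclease strand selection);
* predicting whether an existing library will work on a related species,
  from the mismatch fraction of pairwise rRNA alignments;
* screening probes against an annotated transcriptome for off-targets;
* simulating probe-directed depletion of a fragmented total-RNA pool with
  per-read ground truth;
* computing the depletion-performance and transcriptome-consistency
  statistics used to judge such experiments.

## Probe design

`tile_sequence()` splits a gene of length $L$ into
$k = \lceil L / t \rceil$ abutting tiles for a target tile length $t$
(default 50 nt). Tile lengths are as equal as possible — every tile has
length $\lfloor L/k \rfloor$ or $\lfloor L/k \rfloor + 1$ — with the longer
tiles placed 5'-first. This convention guarantees complete coverage with no
tile more than one base away from its neighbors' length; published probe
sets built with other boundary conventions can differ by a probe or two for
the same input, which is why probe *counts* should be compared only under a
stated convention. `design_oligo_library()` emits the reverse complement of
every tile, ordered 16S then 23S and 5' to 3' along each gene, pooled
equimolarly; concatenating the reverse complements of one gene's probes in
order reconstructs the gene exactly, which the test suite asserts for
random lengths.

Amplicon probes are modeled in two steps. `in_silico_pcr()` scans a template
for the leftmost forward-primer site and the nearest downstream
reverse-primer site. IUPAC degeneracy codes in primers match any compatible
template base; up to 2 internal mismatches per primer are tolerated by
default, but the 3'-terminal base must match exactly — polymerase extension
is blocked by a 3' mismatch, and making the terminal base strict keeps the
simulated priming realistic while the internal budget stays configurable.
`lambda_digest()` then returns the strand *not* tagged as 5'-phosphorylated.
Because the forward primer carries the phosphate, the surviving strand is
antisense to the rRNA — the correct orientation for RNase H depletion.

Universal primer pairs (8F/1541R for 16S, 10F/2756R for 23S) are accepted as
configuration inputs; their sequences are supplied by the user.

## Cross-species applicability

Whether a probe library designed for species A depletes the rRNA of species
B is predicted from sequence similarity alone. The two 16S sequences (and
separately the two 23S sequences) are aligned end-to-end; the *overall
mismatch percentage* is

$$100 \times \frac{\#\{\text{columns where the characters differ, gaps
included}\}}{\text{alignment length}}$$

A gap run of length $g$ counts as $g$ mismatch columns. The library is
predicted applicable when the mean of the 16S and 23S percentages is below
10%. Per probe, the tile is mapped through the alignment to a contiguous
column block (gap columns are assigned to the tile owning the nearest
preceding non-gap position, i.e. to the 5' tile at boundaries) and the same
ratio is computed per block; probes below 25% tile mismatch are counted as
"locally effective". Both thresholds are arguments.

The alignment itself is a standard step, delegated to
`Biostrings::pairwiseAlignment` (global, match +1, mismatch −1, gap open
−4, gap extend −1, so a gap of length $g$ costs $4+g$). At the <25%
divergences where the prediction matters, the mismatch fraction is
insensitive to the aligner; the test suite pins the scores to an
independent exhaustive affine-gap DP oracle on short sequences. Tie-breaking
among co-optimal alignments follows the backend's deterministic rule; only
scores, not paths, are guaranteed against the oracle.

## Off-target screening

A probe can direct RNase H against any transcript it hybridizes to, so the
screen looks for transcripts with a window to which the full-length probe
(or its reverse complement) aligns with at most 8 substitutions plus gap
columns — i.e. semi-global unit-cost edit distance at most 8. The search is
*exhaustive within the threshold*: for each probe × strand × transcript a
row-vectorized dynamic program computes, at every transcript position, the
best distance of an alignment consuming the whole probe, and every position
within budget is clustered into loci and reported (one best hit per locus).
There are no heuristic misses by construction, which the tests confirm
against an independent sliding-window oracle.

An exact k-mer index (`build_seed_index()`, default $k = 12$) is used to
skip transcripts that share no seed with the query — but only for queries of
at least $(d+1)\,k$ nt at mismatch budget $d$, the length below which the
pigeonhole argument cannot guarantee an intact seed k-mer. A 50 nt probe at
$d = 8$ sits far below that bound ($9 \times 12 = 108$ nt), so typical
probe screens scan every transcript; the index pays off for long
amplicon-derived probes. Hits are annotated by strand: a "sense" hit means
the probe is antisense to the transcript, the configuration in which RNase
H would actually cleave that transcript.

## The depletion simulator

`make_toy_organism()` builds a random genome with one 16S-like gene
(1400–1600 nt), one 23S-like gene (2800–3000 nt) and a configurable number
of CDSs, with GFF3-compatible annotation, deterministically under a seed.
Each CDS also gets a relative expression level drawn log-normal(0, 1).
This matters: if mRNA fragments were drawn by gene length alone, every CDS
would have the same expected TPM and any between-sample correlation would
be pure noise — the log-normal spread gives the consistency statistics the
orders-of-magnitude signal real transcriptomes have.

`simulate_pool()` draws fragments: rRNA with probability `rrna_fraction`
(default 0.94, the regime typical of un-depleted bacterial total RNA),
split 16S:23S by gene length; otherwise mRNA with probability proportional
to CDS length × expression. Fragment lengths are truncated-normal
(60 ± 15 nt, minimum 25); the start is uniform over positions where the
fragment fits inside its source, so no fragment is shorter than the
minimum. The simulator does not model sequencing error, PCR duplication,
barcodes or adapter chemistry — passing tests says the *metrics* are
computed correctly on idealized reads, not that any aligner would behave
identically on real data.

`apply_depletion()` is a per-fragment step model. Probe tiles whose tile
mismatch is below the 25% local threshold are "eligible"; eligible tiles
are merged into maximal spans, and an rRNA fragment overlapping a merged
span by at least `min_overlap` (20 nt) is removed with probability `p_max`,
everything else with `p_background` (0). The merge matters: under full
cognate tiling a fragment straddling a tile boundary still hybridizes to
the two adjacent probes' combined footprint, so targetability is measured
against the union, and in that limit every rRNA fragment of at least the
minimum overlap is targetable. The mapping from tile mismatch to removal
probability is a declared step-function approximation — the underlying
dose-response is only constrained empirically, not given as an equation —
and all four knobs are configurable.

With rRNA input fraction $p$ and retention $q = 1 - p_{\max}$ under full
coverage, the post-depletion rRNA fraction has closed form
$pq / (pq + 1 - p)$ and the non-rRNA fold enrichment
$(1 - pq/(pq+1-p)) / (1-p)$. At $p = 0.94$, $q = 0.023$ these give 26.5%
and 12.25 — the regime the simulator reproduces and the tests check within
binomial error. Test and script runs use $10^5$ fragments, which keeps the
binomial standard error of the post-depletion fraction near 0.5 percentage
points while running in seconds.

## Depletion and consistency metrics

* **rRNA reads (%)**: 100 × reads mapped to rRNA / total mapped reads.
  Reads classify either from the simulator's truth table or from SAM
  records, mirroring a two-pass pipeline (rRNA references first, remainder
  to the genome). Multi-mapped reads count here but are excluded from CDS
  counting.
* **Fold enrichment** of non-rRNA reads:
  $(1 - p_{\text{after}})/(1 - p_{\text{before}})$.
* **CDS counts**: a read counts for a CDS it overlaps by ≥1 bp on either
  strand; multi-mapped reads and reads overlapping two or more CDSs are
  excluded (the featureCounts-style ambiguity rule). Overlap arithmetic is
  done with GenomicRanges.
* **TPM**: $10^6 \cdot (c_i/\ell_i) / \sum_j (c_j/\ell_j)$; an all-zero
  sample yields all-zero TPM rather than NaN.
* **Consistency**: Pearson $r$, Spearman $r_s$ (average ranks on ties) and
  $R^2 = r^2$ on $\log_{10}(\mathrm{TPM} + 0.1)$; the 0.1 offset keeps
  zero-expression genes finite while compressing their influence. $R^2$ is
  the square of the correlation, not a regression-through-origin $R^2$.
  Q-Q pairs are the matched order statistics of the two transformed
  vectors. The Mann-Whitney shift statistic is reported in two forms
  derivable from the same $U$: rank-biserial $2U/(n_a n_b) - 1$ (the
  primary effect size) and common-language $U/(n_a n_b)$, since more than
  one convention is in circulation.
* **Ordination**: pairwise $r_s$ on transformed TPM, distance
  $d = \sqrt{2 - 2 r_s}$ (the chord distance of the correlation, bounded
  by 2), embedded with classical Torgerson MDS (`stats::cmdscale`).
  Non-metric MDS is deliberately out of scope. Axis signs — the one
  arbitrary degree of freedom — are canonicalized so the first sample is
  non-negative on each axis; three points always embed exactly in 2-D,
  which the tests check to 1e-9. If the second eigenvalue is non-positive
  the ordination degrades to 1-D with a warning.
* **Per-tile depletion efficiency**: per-base coverage gets a pseudocount
  of 0.5 (zero-coverage positions must stay finite), is normalized to each
  sample's non-rRNA mapped total, and the per-base undepleted/depleted fold
  change is averaged within each tile. Larger values mean stronger local
  depletion; the pseudocount is an argument.

## Cost model

Synthesized oligo probe sets have a high up-front cost amortized over many
reactions; amplicon probes cost per reaction. `breakeven_reactions()`
returns the smallest $n$ with
$\text{upfront} + n\,c_{\text{oligo}} \le n\,c_{\text{amplicon}}$ (shared
reagents cancel), both exactly and rounded to the nearest ten, plus the
simpler upfront/amplicon ratio — the two ways the round number is usually
quoted. With the default inputs (450 up-front, 12,000-reaction yield, 4.98
amplicon, 12.90 shared) the exact break-even is 92 and the per-reaction
totals are ~13 (oligo) and 17.88 (amplicon) currency units.

## Numerical and degenerate-input choices

* U and T are equivalent on input; sequences are canonicalized to DNA at
  parse time and the writer restores the RNA alphabet only for records
  flagged as RNA input.
* Coordinates are 0-based half-open internally (tiles), 1-based inclusive
  in all file interfaces (FASTA/GFF3/SAM/probe sheets).
* All randomness flows through explicit integer seeds; simulator outputs
  are byte-identical across runs for a fixed seed, and the command-line
  interface exposes `--seed` and a `--deterministic` flag that suppresses
  timestamps in output headers.
* `fold_enrichment()` is undefined at 100% rRNA before depletion and errors
  rather than returning infinity; `rrna_fraction()` errors on zero mapped
  reads; `consistency()` requires at least 3 CDSs.

## Known limitations

* The applicability rule is a threshold on a sequence statistic; it does
  not model hybridization thermodynamics, probe secondary structure or
  RNase H kinetics.
* The off-target mismatch criterion is applied to full-probe alignments; a
  local-alignment (HSP-style) criterion would only add hits, and partial
  duplex cleavage efficiency is not modeled.
* The simulator's step-function removal model reproduces threshold
  behavior, not the full dose-response between tile mismatch and depletion
  efficiency.
* Probe design for targets other than 16S/23S rRNA works mechanically but
  is untested territory.
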