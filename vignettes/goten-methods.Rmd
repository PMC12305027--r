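---
title: "Methods: single-nucleus genotyping from long-read amplicons"
author: "goten authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-nucleus genotyping from long-read amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goten)
```

# Overview

`goten` genotypes targeted mosaic SNVs in single nuclei from long-read
amplicon sequencing of barcoded 10X cDNA. Each amplicon read is expected to
contain, in order: a constant anchor (the partial read-1 primer retained in
the cDNA), a 16-nt cell barcode, a 12-nt UMI, and the amplified transcript
sequence spanning the variant. The pipeline converts a FASTQ of such reads
plus the matched short-read evidence into per-cell `ref`/`mut`/`no-call`
labels and per-cell-type enrichment statistics.

This vignette documents the statistical model, every tunable parameter with
its default and rationale, the numerical choices, what the simulator does
and does not emulate, and known limitations.

# Tagging model

The anchor is located by a semi-global edit-distance search (free gaps in
the read, full pattern consumed) on both strands; a hit is accepted when
its edit count is at most `ceiling(0.15 * nchar(anchor))` (4 edits for the
22-nt default anchor). Levenshtein distance, not Hamming, is used
throughout because nanopore errors are indel-dominated; a Hamming search
would lose the cassette frame after a single insertion. Ties between
strands break toward `+` in `findAnchor()`; in `tagReads()` a read whose
two strands carry *equally good* acceptable hits is instead rejected as a
potential chimera (reason `no-anchor`) — a deliberate guard, since a
genuine cassette matches one orientation only.

Barcodes are corrected against the whitelist with `maxCbcEdits = 1`:
an exact match always wins; otherwise the unique entry at distance 1 is
taken and a tie is `cbc-ambiguous`. One edit balances the nanopore error
rate against collision risk in a 16-nt barcode universe. Base qualities are
ignored during correction — nanopore per-base qualities are too poorly
calibrated at this scale to justify a quality-weighted distance. For the
common (`maxCbcEdits = 1`, fixed-length) case the implementation uses a
pigeonhole prefilter: distance 1 between equal-length strings is a single
substitution, so a candidate must match either barcode half exactly; this
is an exact speedup, verified in the tests against a brute-force scan.

Rejection reasons (`no-anchor`, `cbc-unmatched`, `cbc-ambiguous`,
`too-short`) are counted and reported in the run manifest so the tagging
yield is always auditable.

# Allele readout

The payload (read sequence downstream of the UMI, in anchor orientation) is
aligned to the *amplicon reference* — not the genome — with a semi-global
alignment (free end gaps, match 2, mismatch −4, gap open 4, extend 2). An
alignment is accepted when identity over the aligned span is ≥ 0.75 and the
span covers the variant ± 15 nt; both thresholds are config. The 0.75
identity floor admits honest ~10–15% error long reads while rejecting
off-target amplicons; the ±15 nt window ensures the variant column is
embedded in real alignment, not an end-gap artifact. Payloads under 30 nt
are never aligned.

The base observed at the variant column is classified `ref`, `alt`,
`other` (third base), or `missing` (column deleted or uncovered). `other`
observations are retained in outputs — they are direct evidence of the
local error rate — but never count toward either allele. Variant
bookkeeping is 0-based within the amplicon; 1-based positions in user
config are converted at load time. A coordinate-convention test verifies
that adding flanks to the amplicon (with the offset shifted accordingly)
leaves every call unchanged.

# UMI consensus

Within each cell, UMI labels are first merged directionally: `u2` is
absorbed by `u1` when their edit distance is ≤ 1 and
`reads(u1) >= 2 * reads(u2) - 1`, processing UMIs in descending read count
(then lexicographic) order. This is the standard directional rule for
amplification-error UMI networks; the count condition prevents two genuine
molecules that happen to be neighbors from collapsing.

Each (cell, UMI) group is then collapsed: `other`/`missing` reads are
dropped, each allele is weighted by `sum(1 - 10^(-q/10))` over its reads,
and the heavier allele wins; exact ties are discarded rather than broken
arbitrarily. The consensus error probability multiplies the error
probabilities of the consensus-supporting reads (independent errors) and is
floored at `epsilonFloor = 0.005`. The floor matters: nanopore quality
strings are overconfident at context-dependent error hotspots, and an
unfloored product of several Q20 reads would claim error rates below
1e-6 that the instrument cannot deliver.

# Bayesian per-cell genotype

The genotype space is {ref-hom, het-mut}. Alt-homozygosity is excluded by
design: the targeted lesional variants are heterozygous somatic gain-of-
function variants, and restricting the space improves power. Each UMI
consensus is an independent Bernoulli draw:

* under ref-hom, `P(alt) = eps_i` (the consensus error);
* under het-mut, `P(alt) = beta (1 - eps_i) + (1 - beta) eps_i`.

`beta` is the expected alt-allele expression fraction in a het cell
(default 0.5, balanced allelic expression). It is exposed as config
precisely because allelic imbalance and transcriptional bursting can skew
transcript ratios; making it a parameter makes the assumption testable.
The prior `piMut` defaults to 0.5 (uninformative); where a bulk VAF is
available, `2 * VAF` is a natural informative choice for a heterozygous
variant.

The posterior is computed in log space with a log-sum-exp normalization;
the tests require agreement with a naive product-arithmetic oracle to
1e-10 across all evidence configurations with ≤ 6 UMIs and error rates
in {0.005, 0.01, 0.05}, including heterogeneous per-UMI errors.

Calls: `mut` requires `posterior >= tau` (default 0.95); `ref` requires
`1 - posterior >= tau` **and** at least `minUmisRefCall = 2` ref-supporting
UMIs. The support floor exists because a het cell expressing only its ref
allele is indistinguishable from ref-hom at low depth (allelic dropout);
demanding two ref molecules before asserting ref-hom is a cheap insurance
against mislabeling true het cells. Everything else is `no-call`.

Two evidence regimes are supported. *High-specificity* keeps only UMI
consensuses whose exact (barcode, UMI, gene) triple occurs in the matched
Illumina tag table — exact, 0-edit matching, because this filter exists
solely to maximize specificity. *High-sensitivity* imposes no Illumina
match. The high-specificity cell set is provably nested in the
high-sensitivity set, and the tests assert this on repeated simulated runs.

# Enrichment and QC

Mut counts are normalized per cell type by the number of genotyped cells
(ref + mut) to control for differential genotyping efficiency among types.
Each type is tested with an upper-tail hypergeometric
`P(X >= k_t)` (observed value included — the conventional tail), with the
population restricted by default to variant-carrying types (types with at
least one mut cell), so each type is compared against the other
variant-carrying types; a flag widens the family to all genotyped types.
P-values are BH-adjusted within the tested family, and adjusted p < 0.05 is
the reporting threshold. With a single tested type the p-value is 1 by
construction and a warning is emitted.

`genotypingEfficiencyQc()` fits a maximum-likelihood logistic regression of
genotyping success on log1p target-gene expression plus cell-type
indicators — expression should predict genotyping, since the assay
genotypes cDNA — and flags perfect separation (glm warning, non-convergence
or |coefficient| > 15) as unstable rather than reporting nonsense standard
errors.

# The simulator

`simulateCohort()` emulates: a mosaic cell population (het with probability
`mosaicFraction`; bulk VAF ≈ mosaicFraction/2), cell types from a
categorical distribution, Poisson on-target transcripts per cell with
type-specific means, per-transcript allele draws at `betaTrue` in het
cells, geometric (min 1) reads per UMI to mimic amplification skew, reads
assembled as anchor + barcode + UMI + amplicon with position-independent
substitution and indel errors, random read orientation, a whitelist of the
true barcodes plus 10× decoys to exercise correction, and an Illumina tag
table optionally thinned by a capture probability. Per-base qualities
center on the Phred equivalent of the substitution rate with ~2 points of
jitter, so they are calibrated on average while individual miscalled bases
can carry high quality — the failure mode the epsilon floor addresses.
Fixed seeds give byte-identical outputs, and the caller's RNG stream is
never disturbed.

It does **not** emulate: homopolymer-aware or position-dependent error
profiles, chimeric reads, doublets, ambient RNA, isoform structure, or a
full transcriptome. Passing tests therefore demonstrate correctness of the
algorithms under an idealized error model, not performance on any
particular instrument chemistry; on real data the tagging yield and the
`other`-allele rate should be inspected via the run manifest before
trusting downstream calls.

`simulateConsensusEvidence()` generates evidence at the UMI-consensus level
directly (cells, consensus counts, alleles flipped with a fixed error
probability), bypassing the read layer. It exists to study the genotyper's
operating characteristics at controlled depth and error.

# Study sizes and the recovery analysis

The parameter-recovery study uses consensus-level cohorts of 800 cells at
mosaic fractions 0.30 / 0.20 / 0.05 with consensus error 0.01 and UMI depth
`3 + Poisson(5)` per cell (minimum 3, mean 8). The depth was chosen
analytically, not by trial: at `tau = 0.95` and `beta = 0.5` each ref UMI
contributes a likelihood ratio of only ~2, so a ref call is impossible
below ~5 ref UMIs. At shallow depth ref cells are therefore structurally
no-called while het cells (two alt UMIs suffice) are not, and the
genotyped-mut fraction is biased upward — computing the call probabilities
exactly gives a bias of +0.068 at mean depth 5 versus +0.007 at mean 8 for
30% mosaicism. Mean depth 8 is the regime where both genotypes are called
near-completely and the genotyped-mut fraction is an honest estimate of
mosaicism; it is also a realistic yield for a targeted amplicon over a
captured transcript.

Read-level test cohorts use 20–250 cells with ~6 transcripts per cell and
2–2.5 reads per UMI (a few thousand reads), which exercises every code path
while keeping the full suite fast on a single CPU. The null calibration of
the enrichment test uses six types of 350–500 genotyped cells over 1,000
replicates; at these counts the hypergeometric's discreteness is mild and
the observed fraction of raw p < 0.05 sits near the nominal 0.05 (the test
is conservative by construction, so the observed rate falls slightly
below).

# Numerical choices

* Likelihoods in log space with log-sum-exp; posterior normalization
  asserted to 1e-12.
* Exact weight ties in UMI consensus discard the UMI; equal-edit strand
  ties reject the read (chimera guard); equal-distance barcode candidates
  return ambiguous. Degenerate inputs (empty tag tables, empty consensus
  sets, single tested types, zero denominators) return empty results,
  warnings, or `NA` — never silent wrong numbers.
* All output tables are written sorted by primary key, so identical runs
  are byte-identical.
* Mut fractions are reported as percentages to one decimal, matching the
  convention of the per-case summaries.

# Limitations

* SNV targets only; indel or multi-nucleotide variants would need a
  different allele readout, and phasing is out of scope.
* One variant target per run; joint genotyping across loci in the same
  cell is not modeled.
* The two-state genotype space is wrong for loci that can be alt-
  homozygous (e.g. copy-neutral LOH); use the config to widen `piMut`
  cautiously, or do not apply the tool there.
* The published per-cell-type count table behind the headline enrichment
  p-value is distributed only in an access-restricted supplement, so the
  enrichment reproduction in the test suite runs on simulated and worked
  example counts instead.
* Genotyping efficiency depends on expression; rare or lowly expressing
  cell types are under-genotyped, and the QC regression should be
  consulted before interpreting per-type enrichment.
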