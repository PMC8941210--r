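---
title: "Detecting exon skipping in gene-targeted long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting exon skipping in gene-targeted long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicegap)
```

## Scope and model of the data

`splicegap` analyses long cDNA reads from a *single* target transcript.
Because the reference is the mRNA, not the genome, splicing differences
between a read and the reference appear as plain alignment features:

* a **skipped exon** is a reference deletion whose endpoints coincide with
  annotated exon boundaries (junction positions on the mRNA);
* an **alternative 3′/5′ splice site** ("partial skipping") is a deletion
  with exactly one endpoint off a boundary;
* long-read sequencing error contributes mismatches and *short* indels,
  typically 1–5 nt — two orders of magnitude below exon scale.

All internal coordinates are 0-based half-open (BED convention); report
output is 1-based inclusive, and the conversion happens only at I/O.
Multi-transcript gene models and genome-to-transcript projection are out
of scope.

## Alignment

Reads are aligned with an affine-gap semi-global scheme (the read is
consumed in full; end gaps on the reference are free), the natural
geometry for amplicon cDNA reads that are subsequences of the transcript.
The engine is `Biostrings::pairwiseAlignment(type = "global-local")`; the
test suite checks its scores against an independent brute-force dynamic
program on short pairs. Default scoring is match +2, mismatch −4, gap open
−4 (charged once per gap) and extend −1 per base. The heavy open and light
extension make one long deletion cheaper than scattered short gaps, which
is exactly the splice signal the detector needs; all values are
config-exposed. Reads scoring below 0 (e.g. reverse complements) are
flagged unaligned. Externally produced SAM/BAM is ingested through
Rsamtools instead, with unmapped/secondary/supplementary records dropped
and counted.

**Gap placement.** When the bases flanking a deletion repeat across the
junction, equally optimal alignments place the gap anywhere in a small
window. Among score-equivalent placements the pipeline picks the one
minimizing the total distance to annotated exon boundaries (ties to the
leftmost) — the annotation-aware analogue of conventional indel
left-normalization. Non-equivalent placements are never altered, so the
step can only resolve ambiguity, not invent boundary-exact gaps.

## Quality filter

An alignment is retained iff

$$\ln\left(\frac{\mathrm{AlignedBases}}{\mathrm{CigarInstructions}}\right) \ge 4,$$

i.e. at least $e^4 \approx 54.6$ read bases aligned opposite reference
bases per CIGAR run. Error-riddled alignments accumulate runs without
gaining aligned bases, so the ratio falls; clean long alignments pass
easily. Neither term has a universal definition, so both conventions are
switchable: by default `AlignedBases` counts M/=/X bases (insertions and
clips excluded) and `CigarInstructions` counts every run including clips —
the most literal reading. The threshold is inclusive and uses the natural
log. The filter is scale-invariant in the ratio and monotone in CIGAR
complexity (both property-tested).

## Gap scoring, event retention, classification

Each deletion run of at least `min_gap = 20` nt becomes a candidate gap.
Twenty is far below the smallest real exon yet far above the error-indel
cap (5 nt), so the floor separates scales rather than tuning sensitivity.
Each gap is mapped to the nearest exon start (for its start) and nearest
exon end (for its end) — ties resolve to the lower exon index — and scored

$$s = \left(1 + |\mathrm{Start} - \mathrm{NearExonStart}| +
  |\mathrm{End} - \mathrm{NearExonEnd}|\right)^{-1/2} \in (0, 1],$$

with $s = 1$ exactly when both endpoints are boundary-exact. Gaps are
grouped by their implied exon span (a gap whose nearest end-boundary
precedes its nearest start-boundary implies no span and is junction noise,
never a candidate); per-gap scores are summed per span, and events with
TotalScore < 1 are discarded. One boundary-exact read, or a handful of
near-exact ones, is thus sufficient support, while isolated noisy gaps are
not. Summation is per gap; this differs from per-read summation only if
one read carries two gaps on the same span, which bridging makes rare.

Per-read quantification is anchored on the *annotated* candidate span (not
each read's own gap), so that all reads are judged against the same
interval: a read is called skipping iff at least 80 % of the span's
positions have no aligned base and at least half of the margin positions
(pooled across the two margins; each margin `round(0.2 × span length)` nt,
minimum 1) are aligned. Reads whose alignments do not cover the span plus
both margins cannot testify either way and are excluded from the PSI
denominator. A per-margin variant of the margin rule is available by
configuration. PSI = 100 × skipping / spanning reads, with a Wilson 95 %
interval attached (an addition beyond the detection rules, labelled as
such).

## Partial (alternative splice-site) events

Within each read, deletions separated by aligned islands of ≤ 3 nt are
bridged iteratively left-to-right — small islands are sequencing or
alignment artifacts splitting one true deletion. A bridged deletion is a
partial-event candidate iff *exactly one* endpoint sits on an annotated
boundary; the boundary tolerance is 0 nt, because alignment jitter is
instead absorbed by the merge step. Candidates merge when both their
start–start and end–end distances are ≤ 3 nt ("respective endpoints",
read as pairing like with like); clusters are connected components of
that relation (transitive closure, deterministic and order-free), with
the modal (start, end) pair as the reported interval and ties resolved to
the smallest coordinates. Clusters supported by fewer than 4 distinct
reads are discarded. Merging precedes the support filter so near-identical
jittered gaps pool their support; support counts reads, not gaps.
Intron-retention calling is out of scope (the simulator can inject
retained introns, but only as truth-table features).

## Coding consequences and amplicons

Deleted CDS length divisible by 3 ⇒ in-frame, removing length/3 codons
(sequence-level: a deletion splitting two codons that re-fuse in frame
still counts length/3, as in 213 nt ⇒ 71 amino acids); otherwise a
frameshift at the first affected codon. Events crossing the CDS start or
end are "truncating" and not codon-scored. In-silico RT-PCR product length
is the primer-span length minus deletions inside it; a deletion covering a
primer site yields "no product" rather than an error, and a deletion
partially overlapping the span has the overlapping portion subtracted with
a warning (a case the detection rules themselves never produce).

## The simulator and what passing tests mean

The simulator emulates a gene-targeted long-read library: a weighted
isoform mixture on one transcript, optional 5′-truncated starts
(incomplete cDNAs), and independent per-base mismatches plus
capped-geometric indels (cap 5 nt, length 1 dominant — far below exon
scale by design). Error rates are **per-base error fractions**, the usual
way long-read error is quoted: an indel of length $L$ counts $L$ errored
bases, so indel events initiate at rate/E[length] per base. One RNG
stream is consumed in read-index order, so enlarging a run never perturbs
earlier reads, and equal seeds give byte-identical FASTA and truth
output.

The bundled `lars_demo_model()` reproduces the scale of the motivating
system — 33 coding exons tiling 3,900 nt with a 213 nt exon 20 (so
skipping it is in-frame, 71 codons) and CDS covering the transcript — with
a fixed-seed random sequence, so no data file ships with the package. The
default study condition for quantification is a 78:22 full:skip mixture at
1 % mismatch + 1 % indel, the skip fraction and error scale of the
leukocyte scenario the pipeline is designed around.

The simulator does *not* model PacBio quality strings, chimeras, polyA
tails, base-composition bias, or systematically homopolymer-anchored
indels. Passing recovery tests therefore demonstrate the detector's
correctness under exon-scale deletions with realistic short-indel noise,
not robustness to every artifact of real libraries.

## Regulator-screen summarizer

rMATS skipped-exon tables are parsed with strict column validation; rows
are filtered at p < 0.01; exon intervals join the transcript annotation by
interval equality within ±1 nt (absorbing 0/1-based discrepancies); and
the change in percent exon skipping is reported as
−100 × IncLevelDifference, since skipping is the complement of inclusion
(the sign convention is recorded in the output's metadata; equivalence to
any specific rMATS replicate mode is deliberately not asserted). Cell
lines are never averaged. IUPAC motif scanning reports every overlapping
hit, 1-based, via degenerate Biostrings matching, property-tested against
a regular-expression oracle.

## Numerical and design choices

* Boundary ties in nearest-boundary mapping go to the lower exon index
  (determinism; ties are otherwise arbitrary).
* `which.min`-style first-minimum semantics make all tie-breaks
  reproducible.
* Margins clipped at transcript ends; a span whose margins fall entirely
  outside the transcript excludes its reads from the denominator with a
  logged message.
* Zero reads, empty gap sets, empty catalogs and header-only rMATS files
  all return typed empty results rather than errors.
* The pipeline result is a classed S3 object (`splicegap_run`) with
  `print`, `summary` and `plot` (coverage) methods; `run_pipeline()`
  writes every table as TSV plus a JSON manifest recording all thresholds
  actually used (schema in `inst/extdata/output_schema.tsv`).

## Problem sizes used in the shipped checks

Unit and property tests run on small synthetic transcripts (0.9–2.4 kb)
with tens to hundreds of reads; the parameter-recovery property uses
3 seeds × 3 skip fractions × 250 reads on a 2.4 kb model, and the
headline end-to-end check uses 1,000 reads on the full 3.9 kb demo model
— sizes chosen so the whole suite exercises every stage, alignment
included, in a few minutes of one CPU. Estimates are compared against the
realized per-run truth at a 3-percentage-point tolerance.

## Known limitations

* The quality filter interacts with read length: for a ~3.7 kb read the
  pass boundary sits near a 1 % indel fraction, so slightly shorter
  (skipped) reads pass marginally more often. At the default conditions
  this length-differential retention biases PSI upward by well under one
  percentage point; at substantially higher error rates the filter, as
  specified, removes most reads.
* Pairwise alignment (not multiple alignment) is used; per-read gap
  extraction is exact for this geometry, but reads are never polished
  against each other.
* Exon-anchored classification cannot distinguish two different partial
  events inside the same exon span in a single read call; the
  partial-event table carries that resolution instead.
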