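# splicegap

Detection, scoring and quantification of exon-skipping events in
gene-targeted long-read cDNA sequencing.

## The problem

Gene-targeted long-read libraries (e.g. PacBio amplicon sequencing of a
single transcript such as the ~3.9 kb, 33-exon leucyl-tRNA synthetase
mRNA) capture full-length isoforms, so alternative splicing shows up
directly as *reference deletions* in transcript-space alignments: a
skipped exon is a clean deletion whose endpoints coincide with annotated
exon boundaries, while an alternative 3′/5′ splice site leaves exactly one
endpoint off a boundary. The difficulty is separating these splice
deletions from the small indels that dominate long-read error.
`splicegap` implements that separation as a reusable, fully tested
pipeline for anyone analysing targeted long-read cDNA data (or wanting a
transparent reference implementation of this class of analysis).

## The method

Reads are aligned semi-globally (read consumed in full, reference end gaps
free; affine gaps: match +2, mismatch −4, open −4 once per gap, extend −1)
to the transcript. Then:

1. **Quality filter.** An alignment is kept iff
   `ln(AlignedBases / CigarInstructions) ≥ 4`
   — alignments shredded into many CIGAR runs per aligned base are
   error-riddled and discarded (ratio ≥ e⁴ ≈ 54.6).
2. **Gap scoring.** Each deletion gap of ≥ 20 nt is mapped to its nearest
   exon boundaries and weighted by the gap-quality score
   `(1 + |Start − NearExonStart| + |End − NearExonEnd|)^(−1/2)`,
   which equals 1 exactly at boundary-exact gaps and decays with the total
   offset.
3. **Event retention.** Gaps grouped by their implied exon span are summed
   into a TotalScore; events with TotalScore < 1 are discarded.
4. **Per-read classification.** A read skips a candidate exon span iff
   ≥ 80 % of positions inside the span carry no aligned base and ≥ 50 % of
   the positions in the two margins (each 20 % of the span length) are
   aligned; reads not spanning exon + margins are excluded from the
   denominator. Percent skipping (PSI) is reported with a Wilson 95 % CI.
5. **Partial events.** Within-read deletions separated by aligned islands
   ≤ 3 nt are bridged; deletions with exactly one off-boundary endpoint
   are merged when both endpoints lie ≤ 3 nt apart (transitive closure,
   modal interval) and reported when supported by ≥ 4 distinct reads.
6. **Annotation.** Coding consequences (in-frame vs frameshift, amino
   acids removed = deleted CDS length / 3), in-silico RT-PCR amplicon
   sizes, an isoform catalog (LSV1, LSV2, … by abundance), and skip/other
   feature co-occurrence counts.

A synthetic-read simulator with per-read ground truth (isoform mixture,
5′ truncation, per-base mismatch and capped geometric indel errors) makes
every stage testable end to end, and an rMATS skipped-exon summarizer plus
IUPAC motif scanner cover knockdown-screen reanalysis.

## Worked example

```r
library(splicegap)

model <- lars_demo_model()        # synthetic 33-exon, 3,900 nt transcript
cfg <- sim_config(200,
  isoforms = list(full = isoform_spec(), skip20 = isoform_spec(20L)),
  weights = c(0.78, 0.22),
  mismatch_rate = 0.01, insertion_rate = 0.005, deletion_rate = 0.005,
  seed = 42)
sim <- simulate_reads(model, cfg)
run <- run_pipeline(model, reads = sim$reads, out_dir = "run1")
run
#> splicegap run on SYN_LARS_LIKE
#>   alignments: 200 ( 0 unaligned; 17 failed QC )
#>   skip events retained: 1
#>   partial events: 0
#>   isoform catalog entries: 2
run$events
#>    span exon_from exon_to total_score n_gaps n_reads
#> 1 20-20        20      20    33.71343     42      42
run$psi
#>   exon_index n_skip n_span psi_percent ci_lower ci_upper
#> 1         20     42    183    22.95082 17.45167 29.56223
```

The single retained event spans exon 20 with TotalScore 33.7 (42
supporting deletions, most boundary-exact and scoring 1.0); 42 of the 183
reads that span exon 20 plus margins are classified as skipping, i.e.
23.0 % skipping (Wilson 95 % CI 17.5–29.6 %), matching the simulated 22 %
mixture within sampling error. Coding consequence of the event:

```r
frame_consequence(isoform_spec(20L), model)
#> Coding consequence: in_frame
#>   amino acids removed: 71
predict_amplicon(primer_span_around_exon(model, 20L, 721L),
                 isoform_spec(20L), model)$product_length
#> [1] 508
```

Skipping the 213 nt exon 20 is in-frame (213/3 = 71 codons removed), and
an RT-PCR with primers spanning 721 bp around it would yield a 508 bp
product for the skipped isoform.

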