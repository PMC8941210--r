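Package: splicegap
Title: Exon-Skipping Detection and Quantification from Gene-Targeted
    Long-Read Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, scores and quantifies full and partial exon-skipping
    events in transcript-space alignments of gene-targeted long-read cDNA
    sequencing. Reads (FASTA) or alignments (SAM/BAM) against a single
    transcript reference are filtered with a CIGAR-complexity quality score,
    reference deletions are mapped to annotated exon boundaries and weighted
    by a gap-quality score, exon-skipping events are aggregated and retained
    by total score, and individual reads are classified by interior/margin
    base-presence rules. Alternative 3'/5' splice-site (partial skipping)
    events are recovered by island bridging, endpoint classification and
    deletion merging. Coding consequences (frame preservation, amino acids
    removed), in-silico RT-PCR amplicon sizes and percent-skipping (PSI)
    summaries are annotated, and rMATS skipped-exon knockdown screens can be
    summarized alongside IUPAC motif scans. A synthetic long-read simulator
    with per-read ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    graphics,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
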