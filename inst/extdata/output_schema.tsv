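table	column	description
events.tsv	span	implied exon span of the skipping event, "first-last" exon ordinals
events.tsv	exon_from	first exon ordinal in the span
events.tsv	exon_to	last exon ordinal in the span
events.tsv	total_score	sum of per-gap quality scores (1+|dStart|+|dEnd|)^(-1/2); events below the retention threshold are absent
events.tsv	n_gaps	number of supporting deletion gaps
events.tsv	n_reads	number of distinct supporting reads
read_calls.tsv	read_id	read identifier
read_calls.tsv	span	candidate exon span evaluated
read_calls.tsv	exon_from	first exon ordinal of the candidate span
read_calls.tsv	exon_to	last exon ordinal of the candidate span
read_calls.tsv	spanning	TRUE when the read alignment covers the span plus both margins (PSI denominator rule)
read_calls.tsv	interior_unaligned_frac	fraction of span-interior positions with no aligned base
read_calls.tsv	margin_aligned_frac	aligned fraction pooled over the two margins (each 20% of the span length)
read_calls.tsv	skip_call	TRUE when interior >= 0.80 unaligned and margins >= 0.50 aligned
catalog.tsv	label	isoform label: FULL or LSV1.. in descending read count
catalog.tsv	pattern	comma-separated skipped exon ordinals (empty = full length)
catalog.tsv	n_reads	reads carrying this pattern
catalog.tsv	pct	percentage of classified reads
partials.tsv	start	merged deletion start, 1-based inclusive
partials.tsv	end	merged deletion end, 1-based inclusive
partials.tsv	n_members	member gaps in the merged cluster
partials.tsv	support	distinct supporting reads (>= 4 by construction)
partials.tsv	start_at_boundary	TRUE when the start coincides with an annotated exon start
partials.tsv	end_at_boundary	TRUE when the end coincides with an annotated exon end
partials.tsv	nearest_exon	exon ordinal nearest the off-boundary endpoint
partials.tsv	boundary_offset	distance of the off-boundary endpoint from its nearest boundary (nt)
consequences.tsv	span	event exon span
consequences.tsv	status	in_frame / frameshift / truncating / non_coding
consequences.tsv	in_frame	TRUE when the deleted CDS length is divisible by 3
consequences.tsv	aa_removed	amino acids removed (deleted CDS length / 3) for in-frame events
consequences.tsv	deleted_cds_length	deleted CDS nucleotides
psi.tsv	exon_index	exon ordinal
psi.tsv	n_skip	reads called skipping
psi.tsv	n_span	reads spanning the exon plus margins (denominator)
psi.tsv	psi_percent	percent exon skipping, 100 * n_skip / n_span
psi.tsv	ci_lower	Wilson 95% interval lower bound (percent)
psi.tsv	ci_upper	Wilson 95% interval upper bound (percent)
cooccurrence.tsv	skip	per-read exon-skip call (FALSE/TRUE)
cooccurrence.tsv	other_feature	per-read any-other-splicing-feature flag (FALSE/TRUE)
cooccurrence.tsv	Freq	read count in the cell
qc.tsv	read_id	read identifier
qc.tsv	aligned_bases	read bases aligned opposite reference bases (M/=/X)
qc.tsv	cigar_instructions	CIGAR run count (clips included under the default convention)
qc.tsv	ln_ratio	ln(aligned_bases / cigar_instructions)
qc.tsv	retained	TRUE when ln_ratio >= 4
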