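ID	GeneID	geneSymbol	chr	strand	exonStart_0base	exonEnd	upstreamES	upstreamEE	downstreamES	downstreamEE	PValue	FDR	IncLevelDifference	cell_line	target
1	GENE0001	LARS	tx	+	2376	2589	2203	2376	2589	2686	0.0002	0.0031	-0.30	K562	SRSF1
2	GENE0001	LARS	tx	+	2376	2589	2203	2376	2589	2686	0.0040	0.0210	-0.12	HepG2	SRSF1
3	GENE0001	LARS	tx	+	2376	2589	2203	2376	2589	2686	0.0080	0.0450	-0.05	K562	RBM39
4	GENE0001	LARS	tx	+	2376	2589	2203	2376	2589	2686	0.2100	0.5200	-0.22	HepG2	RBM39
5	GENE0001	LARS	tx	+	2027	2203	1868	2027	2203	2376	0.0005	0.0080	0.08	K562	HNRNPC
6	GENE0001	LARS	tx	+	1200	1450	1000	1200	1450	1700	0.0009	0.0120	-0.15	K562	U2AF2
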