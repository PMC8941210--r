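motif	source
GGAGGA	SRSF1_consensus_1
RGAAGAAC	SRSF1_consensus_2
AGGACRRAGC	SRSF1_consensus_3
GAAGAA	SRSF1_consensus_4
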