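cell_cycle_G1_S	synthetic set	CCND1	CDK4	CDK6	E2F1	RB1
cell_division	synthetic set	CCND1	CDK4	MYC	STMN1	PLK1	AURKA
apoptosis	synthetic set	BCL2	TP53	BAX	CASP3
glucose_metabolism	synthetic set	ALDOA	GCK	SLC2A2	PFKM
transcription_regulation	synthetic set	MYC	E2F1	FOXO1	TP53	RB1
amino_acid_transport	synthetic set	SLC7A1	SLC7A5	SLC3A2
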