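mirna	gene	source	evidence
miR-34a-5p	CCND1	dbA	strong
miR-34a-5p	CDK4	dbA	strong
miR-34a-5p	CDK6	dbB	strong
miR-34a-5p	E2F1	dbA	weak
miR-34a-5p	MYC	dbB	strong
miR-34a-5p	BCL2	dbA	strong
miR-122-5p	CCND1	dbB	strong
miR-122-5p	CDK4	dbB	weak
miR-122-5p	CDK6	dbA	strong
miR-122-5p	SLC7A1	dbA	strong
miR-122-5p	ALDOA	dbB	strong
miR-122-5p	MYC	dbA	weak
miR-223-3p	CCND1	dbA	strong
miR-223-3p	CDK4	dbB	strong
miR-223-3p	CDK6	dbB	weak
miR-223-3p	STMN1	dbA	strong
miR-223-3p	MYC	dbB	strong
miR-223-3p	FOXO1	dbA	strong
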