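CCND1
CDK4
CDK6
E2F1
MYC
BCL2
STMN1
FOXO1
SLC7A1
ALDOA
RB1
PLK1
AURKA
TP53
BAX
CASP3
GCK
SLC2A2
PFKM
SLC7A5
SLC3A2
INS
GCG
SST
PDX1
NKX6-1
MAFA
UCN3
CHGA
CHGB
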