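symbol	canonical	hgnc_id
TP53	TP53	HGNC:11998
EGFR	EGFR	HGNC:3236
KRAS	KRAS	HGNC:6407
PIK3CA	PIK3CA	HGNC:8975
BRAF	BRAF	HGNC:1097
NRAS	NRAS	HGNC:7989
RET	RET	HGNC:9967
ALK	ALK	HGNC:427
ROS1	ROS1	HGNC:10261
MET	MET	HGNC:7029
ERBB2	ERBB2	HGNC:3430
ERBB4	ERBB4	HGNC:3432
AKT1	AKT1	HGNC:391
PTEN	PTEN	HGNC:9588
STK11	STK11	HGNC:11389
KEAP1	KEAP1	HGNC:23177
NF1	NF1	HGNC:7765
RB1	RB1	HGNC:9884
CDKN2A	CDKN2A	HGNC:1787
ATM	ATM	HGNC:795
APC	APC	HGNC:583
SMAD4	SMAD4	HGNC:6770
FBXW7	FBXW7	HGNC:16712
NOTCH1	NOTCH1	HGNC:7881
FGFR1	FGFR1	HGNC:3688
FGFR2	FGFR2	HGNC:3689
FGFR3	FGFR3	HGNC:3690
IDH1	IDH1	HGNC:5382
IDH2	IDH2	HGNC:5383
JAK2	JAK2	HGNC:6192
JAK3	JAK3	HGNC:6193
KIT	KIT	HGNC:6342
PDGFRA	PDGFRA	HGNC:8803
ABL1	ABL1	HGNC:76
CTNNB1	CTNNB1	HGNC:2514
DDR2	DDR2	HGNC:2731
GNAS	GNAS	HGNC:4392
GNAQ	GNAQ	HGNC:4390
HRAS	HRAS	HGNC:5173
MAP2K1	MAP2K1	HGNC:6840
MLH1	MLH1	HGNC:7127
MTOR	MTOR	HGNC:3942
SMARCA4	SMARCA4	HGNC:11100
SMO	SMO	HGNC:11119
SRC	SRC	HGNC:11283
VHL	VHL	HGNC:12687
KDR	KDR	HGNC:6307
CSF1R	CSF1R	HGNC:2433
PTPN11	PTPN11	HGNC:9644
ERBB1	EGFR	HGNC:3236
HER1	EGFR	HGNC:3236
HER2	ERBB2	HGNC:3430
NEU	ERBB2	HGNC:3430
HER4	ERBB4	HGNC:3432
HGFR	MET	HGNC:7029
CD246	ALK	HGNC:427
KRAS2	KRAS	HGNC:6407
C-K-RAS	KRAS	HGNC:6407
N-RAS	NRAS	HGNC:7989
HRAS1	HRAS	HGNC:5173
P53	TP53	HGNC:11998
BRAF1	BRAF	HGNC:1097
B-RAF	BRAF	HGNC:1097
PI3K	PIK3CA	HGNC:8975
P16	CDKN2A	HGNC:1787
INK4A	CDKN2A	HGNC:1787
LKB1	STK11	HGNC:11389
MEK1	MAP2K1	HGNC:6840
PRKMK1	MAP2K1	HGNC:6840
FRAP1	MTOR	HGNC:3942
BRG1	SMARCA4	HGNC:11100
VEGFR2	KDR	HGNC:6307
FLK1	KDR	HGNC:6307
C-KIT	KIT	HGNC:6342
CD117	KIT	HGNC:6342
ABL	ABL1	HGNC:76
FMS	CSF1R	HGNC:2433
SHP2	PTPN11	HGNC:9644
CDC4	FBXW7	HGNC:16712
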