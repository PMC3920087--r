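surface	symbol	hgnc_id	is_stop
TP53	TP53	HGNC:11998	FALSE
P53	TP53	HGNC:11998	FALSE
KRAS	KRAS	HGNC:6407	FALSE
MLH1	MLH1	HGNC:7127	FALSE
MSH2	MSH2	HGNC:7325	FALSE
MSH6	MSH6	HGNC:7329	FALSE
PMS2	PMS2	HGNC:9122	FALSE
BRAF	BRAF	HGNC:1097	FALSE
EGFR	EGFR	HGNC:3236	FALSE
BRCA1	BRCA1	HGNC:1100	FALSE
BRCA2	BRCA2	HGNC:1101	FALSE
PIK3CA	PIK3CA	HGNC:8975	FALSE
PTEN	PTEN	HGNC:9588	FALSE
APC	APC	HGNC:583	FALSE
RB1	RB1	HGNC:9884	FALSE
ATM	ATM	HGNC:795	FALSE
NRAS	NRAS	HGNC:7989	FALSE
IDH1	IDH1	HGNC:5382	FALSE
IDH2	IDH2	HGNC:5383	FALSE
FBXW7	FBXW7	HGNC:16712	FALSE
SMAD4	SMAD4	HGNC:6770	FALSE
CDKN2A	CDKN2A	HGNC:1787	FALSE
STK11	STK11	HGNC:11389	FALSE
VHL	VHL	HGNC:12687	FALSE
NF1	NF1	HGNC:7765	FALSE
CTNNB1	CTNNB1	HGNC:2514	FALSE
AKT1	AKT1	HGNC:391	FALSE
HRAS	HRAS	HGNC:5173	FALSE
JAK2	JAK2	HGNC:6192	FALSE
ERBB2	ERBB2	HGNC:3430	FALSE
ALK	ALK	HGNC:427	FALSE
GNAS	GNAS	HGNC:4392	FALSE
NOTCH1	NOTCH1	HGNC:7881	FALSE
CDH1	CDH1	HGNC:1748	FALSE
TSC1	TSC1	HGNC:12362	FALSE
TSC2	TSC2	HGNC:12363	FALSE
SMO	SMO	HGNC:11119	FALSE
FGFR3	FGFR3	HGNC:3690	FALSE
PDGFRA	PDGFRA	HGNC:8803	FALSE
ABL1	ABL1	HGNC:76	FALSE
ARG	ABL2	HGNC:77	TRUE
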