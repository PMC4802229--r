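HR	synthetic stand-in for a curated homologous recombination group	BRCA1	BRCA2	PALB2	RAD51	ATM	BARD1
PRC2	synthetic stand-in	EZH2	SUZ12	EED
PI3K_SIGNALING	synthetic stand-in	PIK3CA	PTEN	PIK3R1	AKT1
CELL_CYCLE_ONCOGENES	synthetic stand-in	CCND1	CCNE1	CDK4	CDK6
CELL_CYCLE_MERGED	synthetic stand-in	RB1	CDKN2A	CCND1	CCNE1	CDK4	CDK6
TOR_SIGNALING	synthetic stand-in	TSC1	TSC2	STK11
MAPK_SIGNALING	synthetic stand-in	KRAS	HRAS	NRAS	BRAF	NF1	MAP2K4
TGF_B_SIGNALING	synthetic stand-in	SMAD4	SMAD2	SMAD3	TGFBR2
RAS_RAF_SIGNALING	synthetic stand-in	KRAS	HRAS	NRAS	BRAF
SWI_SNF	synthetic stand-in	ARID1A	SMARCA1	SMARCA4	ARID2	ARID1B	PBRM1
NOTCH_SIGNALING	synthetic stand-in	NOTCH1	NOTCH2	NOTCH3	FBXW7
WNT_SIGNALING	synthetic stand-in	APC	CTNNB1	AXIN1
CHROMATIN_MODIFIERS	synthetic stand-in	KMT2D	KMT2C	ARID1A	EP300	CREBBP
RTK_SIGNALING	synthetic stand-in	EGFR	ERBB2	ERBB3	FGFR1	FGFR2	MET
APOPTOSIS	synthetic stand-in	TP53	BAX	CASP8
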