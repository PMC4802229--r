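gene	class
KRAS	oncogene
ERBB2	oncogene
CCND1	oncogene
PIK3CA	oncogene
MYC	oncogene
EGFR	oncogene
BRAF	oncogene
NOTCH2	oncogene
NRAS	oncogene
TP53	tumor_suppressor
RB1	tumor_suppressor
SMAD4	tumor_suppressor
ARID1A	tumor_suppressor
NF1	tumor_suppressor
FBXW7	tumor_suppressor
MAP2K4	tumor_suppressor
STK11	tumor_suppressor
CDKN2A	tumor_suppressor
SMARCA4	tumor_suppressor
PTEN	tumor_suppressor
APC	tumor_suppressor
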