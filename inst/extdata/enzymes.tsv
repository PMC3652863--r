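name	recognition	cut_top	cut_bottom
NarI	GGCGCC	2	4
NotI	GCGGCCGC	2	6
FspI	TGCGCA	3	3
EcoRI	GAATTC	1	5
HindIII	AAGCTT	1	5
PstI	CTGCAG	5	1
SmaI	CCCGGG	3	3
BamHI	GGATCC	1	5
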