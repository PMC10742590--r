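name	pattern	category
Box 4	ATTAAT	light
G-box	CACGTG	light
GT1-motif	GGTTAA	light
TCT-motif	TCTTAC	light
AE-box	AGAAACAA	light
chs-CMA1a	TTACTTAA	light
AAGAA-motif	GAAAGAA	light
ABRE	ACGTG	hormone
CGTCA-motif	CGTCA	hormone
TGACG-motif	TGACG	hormone
TCA-element	CCATCTTTTT	hormone
TATC-box	TATCCCA	hormone
LTR	CCGAAA	stress
MBS	CAACTG	stress
ARE	AAACCA	stress
TC-rich repeats	GTTTTCTTAC	stress
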