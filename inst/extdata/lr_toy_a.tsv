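ligand	receptor
TGFB1	TGFBR1
Tgfb1	Tgfbr1
TGFB1	TGFBR1_TGFBR2
IGF1	IGF1R
VEGFA	KDR
CCL2	CCR2
EGF	EGFR
WNT5A	FZD5
FGF2	FGFR1
IL6	IL6R
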