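ligand	receptor
TGFB1	TGFBR1
IGF1	IGF1R
VEGFA	KDR
EGF	EGFR
PDGFB	PDGFRB
WNT5A	FZD5
IL6	IL6R+IL6ST
FGF2	FGFR1
CXCL12	CXCR4
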