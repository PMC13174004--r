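PW_GROWTH	growth factor signaling	EGF	EGFR	FGF2	FGFR1	IGF1	IGF1R
PW_TGFB	TGF-beta signaling	TGFB1	TGFBR1	TGFBR2	SMAD2
PW_CHEMOKINE	chemokine signaling	CCL2	CCR2	CXCL12	CXCR4
PW_WNT	WNT signaling	WNT5A	FZD5	LRP6
PW_NOTCH	NOTCH signaling	DLL1	NOTCH1	JAG1
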