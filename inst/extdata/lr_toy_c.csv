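partner_a,partner_b
TGFB1,TGFBR1
IGF1,IGF1R
EGF,EGFR
FGF2,FGFR1
VEGFA,FLT1
WNT5A,FZD5
DLL1,NOTCH1
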