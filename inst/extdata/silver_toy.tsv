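pathway_id	label	citation
PW_GROWTH	supported	review evidence
PW_TGFB	supported	functional evidence
PW_CHEMOKINE	not_supported	contradicted in context
PW_WNT	unknown	no evidence located
PW_NOTCH	not_supported	implausible in context
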