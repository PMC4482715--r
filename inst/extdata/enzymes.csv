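name,recognition,cut_offset_top
BslI,CCNNNNNNNGG,7
EcoRI,GAATTC,1
HindIII,AAGCTT,1
XhoI,CTCGAG,1
BamHI,GGATCC,1
MboI,GATC,0
AluI,AGCT,2
DdeI,CTNAG,1
HinfI,GANTC,1
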