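code,category
FR,dairy
HO,dairy
HF,dairy
JE,dairy
AY,dairy
MY,dairy
KE,dairy
NR,dairy
SR,dairy
CH,continental_beef
LM,continental_beef
SI,continental_beef
BB,continental_beef
BA,continental_beef
PT,continental_beef
SA,continental_beef
AU,continental_beef
RM,continental_beef
PI,continental_beef
AA,british_irish_beef
HE,british_irish_beef
SH,british_irish_beef
GA,british_irish_beef
DX,british_irish_beef
IM,british_irish_beef
WB,british_irish_beef
LH,british_irish_beef
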