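element,contribution
C,0.36
H,0.11
N,-0.60
O,-0.63
S,0.26
P,-0.50
F,0.22
Cl,0.49
Br,0.60
I,0.89
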