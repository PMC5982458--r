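reference,ABS,Dissolvable,PLA
ABS,1,0.62,0.92
Dissolvable,0.62,1,0.51
PLA,0.92,0.51,1
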