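actual,NL,ML,HL,SL
NL,22,1,1,0
ML,15,147,0,0
HL,3,0,158,0
SL,1,0,0,179
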