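actual,NL,ML,HL,SL
NL,23,17,1,1
ML,1,115,12,4
HL,1,9,153,0
SL,0,0,0,190
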