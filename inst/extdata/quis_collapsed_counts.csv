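+s,+c,N,-p,-r
36,23,0,0,0
22,164,10,4,1
3,13,47,2,5
0,5,2,7,0
3,1,0,0,6
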