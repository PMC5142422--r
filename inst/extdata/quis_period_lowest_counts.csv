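+s,+c,N,-p,-r
2,4,0,0,0
1,9,2,0,1
0,2,2,1,0
0,0,0,0,0
0,0,0,0,1
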