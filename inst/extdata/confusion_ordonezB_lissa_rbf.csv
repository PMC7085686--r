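8,0,0,0,3,0,0,4,0,0
0,3,0,0,0,0,0,0,0,0
0,0,91,0,0,0,0,0,0,1
0,0,0,38,0,0,1,0,1,0
3,0,0,0,3,0,0,3,0,0
0,0,0,0,0,11,0,0,0,0
0,0,1,0,0,0,27,0,0,0
10,8,0,0,5,0,0,32,0,0
1,0,8,0,2,0,1,8,114,2
0,0,4,0,0,0,0,0,0,89
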