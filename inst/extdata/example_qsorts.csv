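statement,P1,P2,P3,P4,P5,P6
1,2,1,1,-1,-2,-1
2,0,0,0,-2,-1,-2
3,0,-1,0,2,1,1
4,-1,-1,-1,0,0,1
5,1,1,2,1,2,2
6,1,2,1,0,1,0
7,0,0,0,1,0,0
8,-1,0,-1,-1,-1,-1
9,-2,-2,-2,0,0,0
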