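V1,V2,V3,V4,group
1,0,0,0,g1
0,0,0,0,g1
1,1,0,0,g1
1,1,0,0,g1
1,0,0,0,g1
1,0,0,0,g1
1,1,0,0,g1
1,0,0,0,g1
1,0,0,0,g1
1,0,0,0,g1
1,0,0,0,g1
1,0,0,0,g1
0,1,0,0,g1
1,1,0,0,g1
1,0,0,0,g1
1,1,0,0,g1
1,1,0,0,g1
0,1,1,0,g1
0,1,0,0,g1
1,1,0,0,g1
1,0,0,0,g1
0,0,0,0,g1
1,1,0,0,g1
1,0,0,0,g1
1,0,0,0,g1
1,1,0,0,g1
1,1,0,0,g1
0,1,0,0,g1
1,0,0,0,g1
0,0,0,0,g1
1,1,0,0,g1
1,0,0,0,g1
1,0,0,0,g1
0,0,0,0,g1
1,0,0,0,g1
0,1,0,0,g1
0,0,0,0,g1
0,0,0,0,g1
0,1,0,0,g1
1,1,0,0,g1
1,1,0,0,g1
1,0,0,0,g1
1,1,0,0,g1
0,1,0,0,g1
0,0,0,0,g1
1,0,0,0,g1
0,0,0,0,g1
1,0,0,0,g1
1,0,0,0,g1
1,1,0,0,g1
0,0,1,1,g2
0,1,1,0,g2
1,0,1,1,g2
1,1,1,0,g2
0,1,0,0,g2
0,0,0,1,g2
0,0,1,1,g2
0,1,1,1,g2
0,0,0,1,g2
0,1,0,0,g2
0,1,0,0,g2
1,1,0,0,g2
0,1,0,0,g2
0,0,0,0,g2
0,1,1,1,g2
0,1,0,1,g2
0,1,0,1,g2
1,1,1,0,g2
0,0,0,0,g2
0,1,1,1,g2
0,1,0,1,g2
0,1,1,1,g2
0,1,1,1,g2
0,1,1,0,g2
0,1,1,1,g2
0,1,0,0,g2
0,1,1,1,g2
0,0,1,0,g2
0,1,0,1,g2
1,1,0,1,g2
0,1,1,1,g2
0,0,0,0,g2
0,0,0,1,g2
0,1,1,1,g2
0,1,1,1,g2
0,1,0,1,g2
1,1,0,0,g2
0,0,0,1,g2
0,0,0,1,g2
0,1,0,1,g2
0,0,1,1,g2
0,1,1,0,g2
1,0,0,1,g2
1,1,0,0,g2
0,1,1,1,g2
1,1,1,1,g2
0,1,1,1,g2
0,1,0,1,g2
0,1,1,1,g2
0,0,1,1,g2
1,0,1,1,g3
0,0,1,1,g3
1,0,1,1,g3
1,0,1,1,g3
0,0,1,1,g3
0,0,1,1,g3
1,1,1,1,g3
1,1,1,1,g3
1,1,1,1,g3
0,0,1,0,g3
0,0,1,1,g3
1,1,1,1,g3
0,0,1,1,g3
0,0,1,1,g3
0,0,1,1,g3
0,0,1,1,g3
0,0,0,1,g3
1,1,1,1,g3
0,0,1,1,g3
1,1,1,1,g3
1,1,1,1,g3
0,0,1,0,g3
1,1,1,1,g3
0,0,1,0,g3
1,1,1,1,g3
1,0,1,1,g3
0,0,1,1,g3
1,0,1,1,g3
1,1,1,1,g3
1,0,1,1,g3
1,1,1,1,g3
1,0,1,0,g3
1,0,1,0,g3
0,0,1,0,g3
1,1,1,1,g3
1,1,1,1,g3
0,0,1,1,g3
1,0,1,0,g3
0,0,1,1,g3
1,1,1,1,g3
1,1,1,1,g3
1,0,1,1,g3
1,1,1,1,g3
0,0,1,1,g3
1,0,1,1,g3
0,0,1,1,g3
1,1,1,1,g3
1,0,1,1,g3
1,0,1,0,g3
1,1,1,1,g3
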