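"pressure_mmhg","flow_fraction"
0,0
10,0.08
20,0.2
30,0.38
40,0.56
50,0.74
60,0.9
70,1
100,1
120,1
150,1
170,1.12
200,1.28
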