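frequency_khz,threshold_db
0.25,104
0.5,92
1,80
2,71
4,62
8,54
16,47
32,41
64,36
100,33
125,34
150,45
160,60
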