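frequency_khz,threshold_db
0.1,95
0.2,87
0.5,77
1,71
2,66
4,62
8,59
16,57
30,60
50,75
60,95
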