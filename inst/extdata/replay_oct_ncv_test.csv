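"i","j","accuracy"
0,5,0.73
1,5,0.71
2,2,0.79
3,5,0.75
4,5,0.88
5,2,0.87
6,0,0.94
7,2,0.9
8,8,0.96
9,2,0.86
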