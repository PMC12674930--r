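"i","j","accuracy"
0,2,0.79
1,1,0.71
2,8,0.69
3,5,0.82
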