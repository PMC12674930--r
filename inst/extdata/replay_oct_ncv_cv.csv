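"i","j","m","accuracy"
0,0,NA,0.91
0,1,NA,0.92
0,2,NA,0.89
0,3,NA,0.89
0,4,NA,0.86
0,5,NA,0.93
0,6,NA,0.88
0,7,NA,0.89
0,8,NA,0.91
1,0,NA,0.87
1,1,NA,0.86
1,2,NA,0.87
1,3,NA,0.84
1,4,NA,0.88
1,5,NA,0.89
1,6,NA,0.86
1,7,NA,0.87
1,8,NA,0.89
2,0,NA,0.83
2,1,NA,0.87
2,2,NA,0.91
2,3,NA,0.85
2,4,NA,0.85
2,5,NA,0.89
2,6,NA,0.89
2,7,NA,0.87
2,8,NA,0.89
3,0,NA,0.85
3,1,NA,0.83
3,2,NA,0.88
3,3,NA,0.82
3,4,NA,0.81
3,5,NA,0.9
3,6,NA,0.85
3,7,NA,0.86
3,8,NA,0.86
4,0,NA,0.86
4,1,NA,0.85
4,2,NA,0.85
4,3,NA,0.83
4,4,NA,0.83
4,5,NA,0.88
4,6,NA,0.82
4,7,NA,0.87
4,8,NA,0.86
5,0,NA,0.86
5,1,NA,0.88
5,2,NA,0.89
5,3,NA,0.8
5,4,NA,0.85
5,5,NA,0.89
5,6,NA,0.88
5,7,NA,0.88
5,8,NA,0.88
6,0,NA,0.87
6,1,NA,0.83
6,2,NA,0.82
6,3,NA,0.81
6,4,NA,0.84
6,5,NA,0.82
6,6,NA,0.85
6,7,NA,0.87
6,8,NA,0.85
7,0,NA,0.85
7,1,NA,0.87
7,2,NA,0.9
7,3,NA,0.83
7,4,NA,0.83
7,5,NA,0.9
7,6,NA,0.83
7,7,NA,0.83
7,8,NA,0.88
8,0,NA,0.85
8,1,NA,0.85
8,2,NA,0.88
8,3,NA,0.83
8,4,NA,0.8
8,5,NA,0.87
8,6,NA,0.85
8,7,NA,0.8
8,8,NA,0.89
9,0,NA,0.87
9,1,NA,0.87
9,2,NA,0.89
9,3,NA,0.84
9,4,NA,0.83
9,5,NA,0.87
9,6,NA,0.87
9,7,NA,0.88
9,8,NA,0.88
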