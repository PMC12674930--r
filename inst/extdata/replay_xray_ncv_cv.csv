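"i","j","m","accuracy"
0,0,1,0.53
0,0,2,0.61
0,0,3,0.75
0,1,1,0.66
0,1,2,0.68
0,1,3,0.8
0,2,1,0.69
0,2,2,0.7
0,2,3,0.76
0,3,1,0.67
0,3,2,0.63
0,3,3,0.82
0,4,1,0.5
0,4,2,0.5
0,4,3,0.5
0,5,1,0.69
0,5,2,0.69
0,5,3,0.76
0,6,1,0.5
0,6,2,0.51
0,6,3,0.77
0,7,1,0.7
0,7,2,0.49
0,7,3,0.78
0,8,1,0.5
0,8,2,0.61
0,8,3,0.78
1,0,0,0.5
1,0,2,0.5
1,0,3,0.77
1,1,0,0.8
1,1,2,0.74
1,1,3,0.84
1,2,0,0.6
1,2,2,0.67
1,2,3,0.71
1,3,0,0.67
1,3,2,0.65
1,3,3,0.79
1,4,0,0.51
1,4,2,0.5
1,4,3,0.78
1,5,0,0.76
1,5,2,0.67
1,5,3,0.76
1,6,0,0.77
1,6,2,0.66
1,6,3,0.76
1,7,0,0.77
1,7,2,0.69
1,7,3,0.8
1,8,0,0.8
1,8,2,0.71
1,8,3,0.8
2,0,0,0.5
2,0,1,0.49
2,0,3,0.5
2,1,0,0.81
2,1,1,0.76
2,1,3,0.71
2,2,0,0.7
2,2,1,0.64
2,2,3,0.66
2,3,0,0.71
2,3,1,0.63
2,3,3,0.76
2,4,0,0.5
2,4,1,0.5
2,4,3,0.67
2,5,0,0.7
2,5,1,0.69
2,5,3,0.74
2,6,0,0.75
2,6,1,0.5
2,6,3,0.78
2,7,0,0.74
2,7,1,0.67
2,7,3,0.74
2,8,0,0.81
2,8,1,0.74
2,8,3,0.77
3,0,0,0.54
3,0,1,0.58
3,0,2,0.5
3,1,0,0.8
3,1,1,0.72
3,1,2,0.5
3,2,0,0.67
3,2,1,0.68
3,2,2,0.61
3,3,0,0.69
3,3,1,0.66
3,3,2,0.56
3,4,0,0.5
3,4,1,0.5
3,4,2,0.5
3,5,0,0.73
3,5,1,0.72
3,5,2,0.64
3,6,0,0.73
3,6,1,0.5
3,6,2,0.5
3,7,0,0.51
3,7,1,0.69
3,7,2,0.56
3,8,0,0.81
3,8,1,0.73
3,8,2,0.5
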