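"i","j","m","accuracy"
NA,0,0,0.63
NA,0,1,0.88
NA,0,2,0.85
NA,0,3,0.76
NA,0,4,0.91
NA,0,5,0.97
NA,0,6,0.92
NA,0,7,0.87
NA,0,8,0.94
NA,0,9,0.88
NA,1,0,0.51
NA,1,1,0.91
NA,1,2,0.79
NA,1,3,0.93
NA,1,4,0.9
NA,1,5,0.91
NA,1,6,0.98
NA,1,7,0.84
NA,1,8,0.97
NA,1,9,0.9
NA,2,0,0.77
NA,2,1,0.88
NA,2,2,0.81
NA,2,3,0.91
NA,2,4,0.96
NA,2,5,0.93
NA,2,6,0.92
NA,2,7,0.91
NA,2,8,0.97
NA,2,9,0.92
NA,3,0,0.37
NA,3,1,0.9
NA,3,2,0.82
NA,3,3,0.83
NA,3,4,0.87
NA,3,5,0.91
NA,3,6,0.91
NA,3,7,0.92
NA,3,8,0.98
NA,3,9,0.87
NA,4,0,0.68
NA,4,1,0.89
NA,4,2,0.86
NA,4,3,0.84
NA,4,4,0.78
NA,4,5,0.99
NA,4,6,0.88
NA,4,7,0.86
NA,4,8,0.93
NA,4,9,0.91
NA,5,0,0.77
NA,5,1,0.88
NA,5,2,0.89
NA,5,3,0.79
NA,5,4,0.94
NA,5,5,0.97
NA,5,6,0.92
NA,5,7,0.91
NA,5,8,0.96
NA,5,9,0.93
NA,6,0,0.66
NA,6,1,0.88
NA,6,2,0.81
NA,6,3,0.91
NA,6,4,0.84
NA,6,5,0.95
NA,6,6,0.91
NA,6,7,0.9
NA,6,8,0.97
NA,6,9,0.92
NA,7,0,0.69
NA,7,1,0.87
NA,7,2,0.84
NA,7,3,0.93
NA,7,4,0.85
NA,7,5,0.79
NA,7,6,0.95
NA,7,7,0.86
NA,7,8,0.97
NA,7,9,0.91
NA,8,0,0.64
NA,8,1,0.89
NA,8,2,0.69
NA,8,3,0.94
NA,8,4,0.92
NA,8,5,0.92
NA,8,6,0.97
NA,8,7,0.9
NA,8,8,0.97
NA,8,9,0.9
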