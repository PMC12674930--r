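"i","j","m","accuracy"
NA,0,0,0.71
NA,0,1,0.71
NA,0,2,0.69
NA,0,3,0.7
NA,1,0,0.79
NA,1,1,0.63
NA,1,2,0.71
NA,1,3,0.71
NA,2,0,0.78
NA,2,1,0.7
NA,2,2,0.69
NA,2,3,0.65
NA,3,0,0.75
NA,3,1,0.69
NA,3,2,0.66
NA,3,3,0.8
NA,4,0,0.5
NA,4,1,0.5
NA,4,2,0.59
NA,4,3,0.78
NA,5,0,0.75
NA,5,1,0.74
NA,5,2,0.71
NA,5,3,0.8
NA,6,0,0.73
NA,6,1,0.71
NA,6,2,0.73
NA,6,3,0.77
NA,7,0,0.77
NA,7,1,0.72
NA,7,2,0.63
NA,7,3,0.75
NA,8,0,0.81
NA,8,1,0.74
NA,8,2,0.63
NA,8,3,0.81
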