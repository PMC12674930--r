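"index","architecture","batch_size","learning_rate","decay","momentum","nesterov"
0,"ResNet50",128,0.01,0.01,0.9,"Enabled"
1,"InceptionV3",16,0.001,0.001,0.9,"Disabled"
2,"ResNet50",64,0.01,0.01,0.99,"Enabled"
3,"Xception",16,0.001,0.001,0.5,"Disabled"
4,"ResNet50",64,0.01,0.01,0.5,"Disabled"
5,"ResNet50",32,0.01,0.01,0.99,"Enabled"
6,"ResNet50",32,1e-04,1e-04,0.99,"Disabled"
7,"ResNet50",32,0.01,0.01,0.9,"Enabled"
8,"InceptionV3",64,0.01,0.01,0.5,"Disabled"
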