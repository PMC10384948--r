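fold,accuracy_global,accuracy_benign,accuracy_malignant
1,1,1,1
2,0.95,1,0.667
3,0.95,1,0.875
4,0.842,0.727,1
5,1,1,1
6,0.95,0.933,1
7,0.9,0.933,0.8
8,1,1,1
9,1,1,1
10,1,1,1
11,0.95,1,0.833
12,0.947,0.917,1
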