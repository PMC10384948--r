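fold,auc,precision,recall,f1
1,1,1,1,1
2,0.833,0.972,0.833,0.886
3,0.938,0.962,0.938,0.947
4,0.864,0.864,0.864,0.842
5,1,1,1,1
6,0.967,0.917,0.967,0.937
7,0.867,0.867,0.867,0.867
8,1,1,1,1
9,1,1,1,1
10,1,1,1,1
11,0.917,0.967,0.917,0.937
12,0.958,0.938,0.958,0.945
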