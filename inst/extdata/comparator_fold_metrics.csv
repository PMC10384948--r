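method,fold,auc,accuracy,precision,recall,f1
svm,1,0.833,0.895,0.833,0.933,0.864
svm,2,0.771,0.842,0.771,0.717,0.737
svm,3,0.938,0.947,0.938,0.958,0.945
svm,4,0.958,0.947,0.958,0.938,0.945
plsda,1,0.833,0.895,0.833,0.933,0.864
plsda,2,0.941,0.895,0.941,0.750,0.802
plsda,3,1,1,1,1,1
plsda,4,0.944,0.947,0.944,0.955,0.947
rf,1,1,1,1,1,1
rf,2,0.969,0.947,0.969,0.875,0.912
rf,3,0.887,0.895,0.887,0.887,0.887
rf,4,0.958,0.947,0.958,0.938,0.945
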