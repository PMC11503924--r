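family,input_combination,arm,train_mae,train_r,test_mae,test_r
knn,vi,raw,0.464,0.972,0.754,0.933
rf,vi,raw,0.343,0.986,0.644,0.953
elm,vi,raw,1.033,0.897,1.089,0.893
knn,vi,wt,0.391,0.984,0.716,0.948
rf,vi,wt,0.224,0.992,0.548,0.976
elm,vi,wt,1.018,0.901,1.062,0.908
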