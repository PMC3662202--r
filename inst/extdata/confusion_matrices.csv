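classifier,variant,true,NC,MCI,AD
som,raw,NC,13,2,1
som,raw,MCI,3,12,3
som,raw,AD,1,4,13
som,pca,NC,15,2,0
som,pca,MCI,2,13,5
som,pca,AD,0,3,15
svm,raw,NC,13,0,1
svm,raw,MCI,3,14,3
svm,raw,AD,1,4,13
svm,pca,NC,15,1,0
svm,pca,MCI,2,15,3
svm,pca,AD,0,2,14
psosvm,raw,NC,15,1,0
psosvm,raw,MCI,2,14,3
psosvm,raw,AD,0,3,14
psosvm,pca,NC,16,1,0
psosvm,pca,MCI,1,16,1
psosvm,pca,AD,0,1,16
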