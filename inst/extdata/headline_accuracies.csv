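classifier,variant,task,accuracy
som,raw,AD,76.47
som,raw,MCI,66.67
som,pca,AD,88.24
som,pca,MCI,72.22
svm,raw,AD,76.47
svm,raw,MCI,77.78
svm,pca,AD,82.35
svm,pca,MCI,83.33
psosvm,raw,AD,82.35
psosvm,raw,MCI,77.78
psosvm,pca,AD,94.12
psosvm,pca,MCI,88.89
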