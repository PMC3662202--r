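feature_set,C1,C2,C3,C4,C5,C6,C7,C8
volume,64.16,31.57,4.27,,,,,
shape,48.79,23.39,9.43,6.45,3.28,2.13,1.01,0.73
volume_shape,49.31,19.98,13.62,6.93,4.47,2.35,0.99,0.72
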