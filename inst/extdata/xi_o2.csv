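dose_uM,weight
0,0.1
100,0.1
125,0.1
150,0.1
175,0.1
200,0.1
225,0.1
250,0.1
300,0.1
450,0.1
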