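dose_uM,weight
0,0.0909090909090909
100,0.0909090909090909
125,0.0909090909090909
150,0.0909090909090909
175,0.0909090909090909
200,0.0909090909090909
225,0.0909090909090909
250,0.0909090909090909
300,0.0909090909090909
450,0.0909090909090909
1000,0.0909090909090909
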