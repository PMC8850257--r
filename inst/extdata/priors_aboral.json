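{
  "sets": [
    [1.513, -0.013, 6.103, -0.034],
    [0.9, -0.021, 6.103, -0.052],
    [0.9, -0.021, 8.93, -0.053],
    [0.9, -0.021, 9.7, -0.06],
    [1.1, -0.015, 9.7, -0.072],
    [1.5, -0.015, 11.5, -0.065]
  ],
  "probs": [0.16666666666666666, 0.16666666666666666, 0.16666666666666666,
            0.16666666666666666, 0.16666666666666666, 0.16666666666666669]
}
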