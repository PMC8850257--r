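{
  "sets": [
    [-1.25, 0.004, 1.46, -0.007],
    [-1.5, 0.007, 1.7, -0.01],
    [-1.75, 0.01, 2.0, -0.013],
    [-1.5, 0.004, 1.46, -0.007],
    [-1.0, 0.004, 2.46, -0.007],
    [-1.0, 0.006, 3.46, -0.01]
  ],
  "probs": [0.16666666666666666, 0.16666666666666666, 0.16666666666666666,
            0.16666666666666666, 0.16666666666666666, 0.16666666666666669]
}
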