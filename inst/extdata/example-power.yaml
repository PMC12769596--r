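# Two small power scenarios (increase n_sim for production use).
scenarios:
  - n: 30
    icc: 0.05
    model: 1
    effects: {beta_a: 0.8, beta_b: 0.8, beta_c: 1.6}
    estimators: [lmm, gee, gee-md]
    n_sim: 200
  - n: 60
    icc: 0.30
    model: 2
    effects: {beta_a: 0.8, beta_b: 0.8, beta_c: 2.0}
    estimators: [lmm, gee-md]
    n_sim: 200
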