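# Simulate one standard-design trial: 30 participants, additive effects.
n: 30
icc: 0.05
sigma: 1
effects:
  u: 0
  beta_t: 1
  beta_a: 0.8
  beta_b: 0.8
  beta_c: 1.6
seed: 20260921
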