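# Kinase-rate bifurcation sweep of the T281R variant at default parameters.
model: reduced
variant: T281R
sweep:
  param: k_k
  from: 1.0e-05
  to: 0.1
  n: 41
  log: true
seed: 1
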