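# Calibrated dimensionless base (wild-type) parameter set, reduced model.
# Located by bistability scans: the T281R variant derived from this base
# (k_k * 0.1, k_p = 0) is bistable at lam = 0.02; the wild type is
# monostable for every kinase rate.
k_k: 0.01
k_p: 1.0
V_0: 0.005
V_f: 1.0
K_f: 5.0
h: 1
lam: 0.02
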