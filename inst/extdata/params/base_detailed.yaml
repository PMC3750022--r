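# Calibrated base (wild-type) parameter set, detailed six-species model.
# Effective kinase constant k_cat_t / K_t ~ 0.01 matches the reduced base;
# the T281R variant (k_cat_t * 0.1, k_cat_p = 0) is bistable at lam = 0.02.
V_0: 0.005
V_f: 1.0
K_f: 5.0
h: 1
lam: 0.02
k_a: 1.0
k_on_t: 0.1
k_off_t: 10.0
k_cat_t: 1.11
k_on_p: 1.0
k_off_p: 10.0
k_cat_p: 5.0
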