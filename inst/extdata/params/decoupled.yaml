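# Decoupled variant: autoregulated phoP, constitutive phoQ held at Q_tot.
# k_k reflects the strong inducible promoter context; K_d = .inf means no
# phosphatase-complex sequestration (the monostable reference case); the
# low-K_d analysis uses K_d = 0.1, where a bistable Q_tot band exists.
k_k: 0.1
k_p: 0.0
V_0: 0.005
V_f: 1.0
K_f: 5.0
h: 1
lam: 0.02
Q_tot: 3.0
k_cons: 1.0
K_d: .inf
k_on_p: 10.0
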