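# quick smoke grid for the Monte-Carlo harness: full scenario design at a
# reduced replicate count (expect wide Monte-Carlo error)
beta_diff: [0, 2.174, 5]
sigma2_e: [16, 52.867]
n: [20, 100]
m: 2
n_sims: 50
seed: 20100408
p_levels: [0.80, 0.85, 0.90, 0.95]
alpha: 0.05
tol: 1.0e-4
methods: [TI]
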