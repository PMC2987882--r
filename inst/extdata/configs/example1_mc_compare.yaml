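# Cross-validation of characteristics against a Monte Carlo histogram on the
# bulk of the autoregulation density at t = 10.
task: mc_compare
model:
  name: autoregulation
  params: {V_max: 1.0, K: 2.0, k_d: 0.01, beta: 4.0}
initial_density:
  - kind: normal
    mean: [2.0]
    cov_diag: [0.2]
grid:
  axes:
    - {lo: 6.0, hi: 16.0, h: 0.25}
time: 10
n_samples: 20000
seed: 1
settings: {rel_tol: 1.0e-8, abs_tol: 1.0e-10}
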