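# Maximum-likelihood estimation of V_max from a single observation x = 5 at
# t = 20, scenario (a): informative joint normal prior on (x0, V_max) with
# mean (2, 1) and diagonal covariance (0.2, 0.01). Expected maximizer ~ 1.
task: profile
model:
  name: autoregulation
  params: {K: 2.0, k_d: 0.01, beta: 4.0}
profile:
  parameter: V_max
  lo: 0.0
  hi: 2.0
  h: 0.05
initial_density:
  - kind: normal
    mean: [2.0, 1.0]
    cov_diag: [0.2, 0.01]
data:
  time: 20
  values: [5.0]
settings: {rel_tol: 1.0e-8, abs_tol: 1.0e-10}
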