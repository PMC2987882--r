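# Maximum-likelihood estimation of V_max, scenario (b): x0 ~ normal(2, 0.2)
# independent of V_max ~ uniform on [0, 2] (no prior information on V_max
# beyond the interval constraint). Expected maximizer ~ 0.2.
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
    mean: [2.0]
    cov_diag: [0.2]
  - kind: uniform
    lower: [0.0]
    upper: [2.0]
data:
  time: 20
  values: [5.0]
settings: {rel_tol: 1.0e-8, abs_tol: 1.0e-10}
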