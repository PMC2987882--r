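# Heavy-tail mass of the autoregulation model: exact density on the
# low-probability interval [0, 10] at t = 50 via the backward-forward
# procedure, integrated by the midpoint rule (expected mass ~ 0.001).
task: region_mass
model:
  name: autoregulation
  params: {V_max: 1.0, K: 2.0, k_d: 0.01, beta: 4.0}
initial_density:
  - kind: normal
    mean: [2.0]
    cov_diag: [0.2]
region:
  axes:
    - {lo: 0.0, hi: 10.0, h: 0.1}
time: 50
settings: {rel_tol: 1.0e-8, abs_tol: 1.0e-10}
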