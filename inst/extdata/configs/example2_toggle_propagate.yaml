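# Genetic toggle switch: propagate an initial grid of characteristics with
# their density values. By t = 10 the initially round normal density has
# contracted onto the slow manifold of the vector field.
task: propagate
model:
  name: toggle_switch
  params: {alpha1: 5.0, alpha2: 5.0, beta1: 2.0, beta2: 2.0, q1: 1.0, q2: 1.0, k_d: 1.0}
initial_density:
  - kind: normal
    mean: [3.0, 3.0]
    cov_diag: [0.1, 0.1]
initial_grid:
  axes:
    - {lo: 2.0, hi: 4.0, h: 0.1}
    - {lo: 2.0, hi: 4.0, h: 0.1}
times: [0, 1, 2, 5, 10]
settings: {rel_tol: 1.0e-8, abs_tol: 1.0e-10}
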