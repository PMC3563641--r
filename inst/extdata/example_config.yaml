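# Example run configuration: discriminate the simple from the hysteretic
# enzyme model under a shared initial state, robustifying the simple model's
# association and catalytic constants.
models:
  A: simple_enzyme
  B: hysteretic_enzyme
params:
  A: {k1: 6.4086, km1: 0.0, k2: 2.0749}
  B: {k1: 0.05, k2: 0.001, k3: 0.06, k4: 0.001, k5: 0.001,
      k6: 6.0, k7: 0.001, k8: 0.001, k9: 0.01, k10: 4.0}
boxes:
  A:
    lower: {k1: 0.5, k2: 0.5}
    upper: {k1: 100.0, k2: 30.0}
design:
  spacing: 26
  n_t: 10
  x0: {S: 1.0, E: 0.02, ES: 0.0, P: 0.0, Ei: 0.02, Ea: 0.0, EiS: 0.0, EaS: 0.0}
  design_x0: [S, E]
space:
  n_t: 10
  x0_bounds:
    S: [0.5, 2.0]
    E: [0.01, 0.05]
objective:
  sigma: 0.01
  step_dt:
    width: 5.0
    center: 10.0
  step_p:
    width: 0.05
    center: 0.025
robust:
  eps_stop: 1.0e-3
  max_iter: 25
  n_starts: 5
  seed: 0
  homotopy:
    enabled: true
    n_steps: 3
    trigger_gap: 0.1
solver:
  rel_tol: 1.0e-8
  abs_tol: 1.0e-10
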