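# Twenty spacer types differing only in failure probability (effectiveness),
# acquired with equal probability alpha_total / 20 = 0.0972 / 20. The
# steady-state distribution peaks on the most effective (lowest-eta) spacer.
model: multi
params:
  f: 1.0
  K: 1.0e+5
  kappa: 1.0e-2
  g: 1.0e-4
  mu: 1.0
  b: 100.0
  alpha_vec: [0.00486, 0.00486, 0.00486, 0.00486, 0.00486, 0.00486, 0.00486,
              0.00486, 0.00486, 0.00486, 0.00486, 0.00486, 0.00486, 0.00486,
              0.00486, 0.00486, 0.00486, 0.00486, 0.00486, 0.00486]
  eta_vec: [0.0005, 0.0009736842, 0.0014473684, 0.0019210526, 0.0023947368,
            0.0028684211, 0.0033421053, 0.0038157895, 0.0042894737,
            0.0047631579, 0.0052368421, 0.0057105263, 0.0061842105,
            0.0066578947, 0.0071315789, 0.0076052632, 0.0080789474,
            0.0085526316, 0.0090263158, 0.0095]
initial_state:
  n0: 1000.0
  n_vec: [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0]
  v: 1.0e+4
simulation:
  t_max: 2.0e+4
sweep:
  alpha_total: [0.001, 0.01, 0.0972, 0.5]
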