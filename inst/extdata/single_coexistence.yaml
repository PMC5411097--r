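# Reference single-spacer coexistence run: a small wild-type inoculum meets
# phage, acquires spacers, bottlenecks, and recovers to a phage-limited
# plateau. All rates in units of the wild-type growth rate (f0 = 1).
model: single
params:
  f0: 1.0
  r: 1.0
  K: 1.0e+5
  kappa: 2.0e-3
  g: 1.0e-5
  eta: 5.0e-3
  alpha: 1.0e-4
  mu: 1.0
  b: 100.0
initial_state:
  n0: 1000.0
  n1: 0.0
  I0: 0.0
  I1: 0.0
  v: 1.0e+4
simulation:
  t_max: 1.0e+4
  n_outputs: 400
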