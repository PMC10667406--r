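# Canonical configuration: a = 16/11, so that the Neimark-Sacker critical
# value is epsilon0 = 0.5 exactly and E2 = (3/11, 3/11) ~ (0.2727, 0.2727).
name: fig1_canonical
params:
  a: 1.4545454545454546
  delta: 0.5
  epsilon: 0.45
initial_states:
- [0.6, 0.2]
- [0.28, 0.3]
sweep:
  eps_lo: 0.19
  eps_hi: 0.6
  n_eps: 120
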