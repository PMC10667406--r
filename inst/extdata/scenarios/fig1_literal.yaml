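# Literal configuration: a = 1.4 as printed in the simulation setting, for
# which epsilon0 = 2/7 ~ 0.2857 and E2 = (0.3, 0.3).
name: fig1_literal
params:
  a: 1.4
  delta: 0.5
  epsilon: 0.45
initial_states:
- [0.6, 0.2]
sweep:
  eps_lo: 0.19
  eps_hi: 0.6
  n_eps: 120
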