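experiment: fig5
input:
  type: frozen_poisson
  n_syn: 2000
  rate: 0.01
  period: 2000
plasticity:
  alpha: 0.9
  eta: 0.5
  tau: 5
n_periods: 200
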