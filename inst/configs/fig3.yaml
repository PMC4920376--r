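experiment: fig3
input:
  type: frozen_poisson
  n_syn: 500
  rate: 0.02
  period: 2000
schedule:
  event_window: [1800, 2000]
  g_E_on: 15
  p_event: 1
plasticity:
  alpha: 0.985
  eta: 0.5
  tau: 9
n_periods: 400
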