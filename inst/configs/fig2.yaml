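experiment: fig2
input:
  type: orthogonal
  n_syn: 500
  period: 2000
schedule:
  event_window: [1800, 2000]
  g_E_on: 15
plasticity:
  alpha: 0.985
  eta: 50
  tau: 9
n_periods: 500
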