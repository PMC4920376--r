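experiment: fig6
plasticity:
  alpha: 0.95
  eta: 1.5
  tau: 9
recurrent:
  n_groups: 4
  group_size: 50
  pulse_ms: 100
  g_E_on: 20
  n_repeats: 300
  recall_ms: 20
  recall_span: 600
  settle_ms: 300
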