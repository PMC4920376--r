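experiment: fig4
plasticity:
  alpha: 0.985
  eta: 0.5
  tau: 9
paired:
  n_stm: 2000
  n_trials: 100
  trial_len: 3000
  target_window: [1500, 1700]
  delay_window: [1300, 1500]
  iti_range: [3000, 10000]
  n_probe: 8
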