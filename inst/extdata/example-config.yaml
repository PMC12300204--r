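# Example gazeid pipeline configuration. Keys override default_config();
# the seed is mandatory and makes the whole run reproducible.
seed: 42
output_dir: gazeid-run
synth:
  n_subjects: 6
  n_sessions: 3
  positions: 40
  dwell_ms: 1000
  amplitude_range: [4, 20]
  blink_rate: 0.05
segment:
  window_len: 303
  segment_len: 100
  g: 3
  x: 25
model:
  kind: lstm
train:
  epochs: 30
  lr: 0.001
  batch_size: 16
eval:
  scale_mode: train
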