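# Minimal experiment configuration.  Every field has a default; omitted
# blocks fall back to the values documented in ?experiment_config.
seed: 1
cohort:
  # either a `source:` path to a cohort CSV, or generator fields:
  n_participants: 10
  play_noise_sd_minutes: 5
  decay_rate: 0.97
label:
  threshold_seconds: 600
window:
  w_max: 10
  fallback: 3
  train_days: 30
augmentation:
  techniques: [none, jitter, scaling, time_warp, jitter_time_warp, scaling_time_warp]
  sigma_jitter: 0.01
  sigma_scaling: 0.1
  sigma_warp: 0.2
  n_knots: 4
  folds: 5
model:
  families: [cnn, lstm, cnn_lstm]
training:
  learning_rate: 0.001
  epochs: 100
  batch_size: 16
  decision_threshold: 0.5
output:
  dir: runs/example
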