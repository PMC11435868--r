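# Example pfmg run configuration. Any omitted key keeps its shipped default.
out_dir: pfmg_out
seed: 1
n_sessions: 2

# synthetic acquisition (2000 samples at 1.35 ms = 2.7 s per recording)
n_trials: 3
samples_per_recording: 2000
sampling_period: 0.00135
noise_sd: 0.35
trial_offset_sd: 0.25
drift_slope: 0.02
quasi_dynamic: false

window:
  length: 100      # samples (~135 ms)
  stride: 50       # 50% overlap

alerts:
  rel_threshold: 0.20
  horizon_s: 1.0

filter:
  order: 5
  band: [0.5, 330.0]   # Hz

selection_fraction: 0.5
models: [GaussianNB, NuSVC, QDA, LDA, RF, K-NN, DT]
protocol: inter_trial   # or inter_session

queue:
  capacity: 10
  theta: 0.75
  hold_last_confident: false

spatial:
  enabled: false
  mode: repeat_rate     # repeat_rate | index_increment | discrete
  gain: 1.0
  step: 10.0
  rate_scale: 0.1
  thresholds: [-10.0, 10.0]
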