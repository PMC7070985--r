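# Example experiment configuration for the emg3d command-line front end.
# Unset fields keep the package defaults (see ?experiment_config,
# ?synth_config, ?training_config).
synth:
  G: 4
  grid: [8, 16]        # rows, cols
  fs: 1000             # Hz
  trial_s: 3
  activity_fraction: [0.3333, 0.6667]
  carrier_band: [20, 400]
  snr_db: 10
  n_trials_per_gesture: 10
  seed: 1
experiment:
  protocol: capgmyo-half-half
  l_cube: 10
  train_stride: 25
  frame_stride: 10
  pool_s: 2
  voting_grid_ms: [50, 100, 150]
  band: [20, 400]
  window_len: 150
  n_kernels: [8, 16, 16]
  fc: [64, 32]
training:
  lr0: 0.1
  batch_size: 32
  max_epochs: 15
  seed: 1
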