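# Example pipeline configuration: two-variant panel at TIRF defaults.
variants:
  WT:
    velocity: 810          # nm/s
    mean_run_length: 3.06  # um
    mean_end_dwell: 0.46   # s
    landing_rate: 0.02     # events / um / s
  S266R:
    velocity: 676
    mean_run_length: 1.54
    mean_end_dwell: 1.41
    landing_rate: 0.02
imaging:
  frame_interval: 0.37037  # s (2.7 Hz)
  pixel_size: 160          # nm
  n_frames: 300
  psf_sigma: 1.1           # px
  signal_amplitude: 400
  background_mean: 100
  background_sd: 20
dataset:
  n_microtubules: 4
  mt_length_range: [6, 10] # um
analysis:
  k_threshold: 3
  duration_convention: k
  end_window: 0
  end_attribution: peak
  min_transloc_frames: 3
stats:
  reference: WT
  n_boot: 10000
  boot_seed: 12345
seed: 1
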