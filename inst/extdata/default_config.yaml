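# vtnet default run configuration (calibrated defaults)
network:
  grid_rows: 20
  grid_cols: 20
  grid_spacing: 0.5
  rf_amplitude: 1.0
  rf_sigma: 0.95549
  lat_ex_amp: 0.15
  lat_in_amp: 0.05
  lat_ex_sigma: 0.45
  lat_in_sigma: 1.2
  sigmoid_slope_unisensory: 3.0
  sigmoid_thresh_unisensory: 3.0
  sigmoid_slope_multisensory: 4.0
  sigmoid_thresh_multisensory: 1.2
  sigmoid_slope_inhibitory: 12.0
  sigmoid_thresh_inhibitory: 0.75
  tau_unisensory: 20.0
  tau_multisensory: 20.0
  tau_inhibitory: 10.0
  callosal_delay: 10.0
  w_ff_tactile: 0.2
  w_ff_visual: 0.2
  w_fb_tactile: 0.1
  w_fb_visual: 0.1
  w_inter: 1.0
  w_inh_tactile: 0.15
  w_inh_visual: 0.15
  detection_threshold: 0.5
  dt: 0.5
  t_max: 600.0
  steady_tol: 1.0e-5
stimuli:
  tactile_strength: 6.0
  visual_bright_strength: 92.2
  noise_variance: 0.2
cohort:
  n_subjects: 16
  reps: 20
  jitter_fraction: 0.4
  jitter_as: sd
master_seed: 1
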