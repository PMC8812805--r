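# Demo study: two small synthetic cohorts, screening task, two fast
# classifier families. See default_pipeline_config() for every field.
panel: {}
profiles:
  beta_deficit: 0.5
  alpha_deficit: 0.55
  between_sample_cv: 0.15
acquisition:
  noise_sd: 0.002
  calibration_shift_ppm: 400.0
  sampling_step: 2.0
  mz_range: [7000.0, 18000.0]
cohort1:
  control: 12
  alpha_thal: 4
  beta_thal: 8
cohort2:
  control: 12
  alpha_thal: 4
  beta_thal: 8
processing:
  smooth_window: 7
  snip_iterations: 60
  snr_min: 3.0
  min_spacing: 10.0
  tolerance_ppm: 3000.0
  is_norm: same_charge
split:
  ratio: [2.0, 1.0]
selection:
  thal_vs_control:
    top_k: 5
methods: [LR, NB]
tasks: [thal_vs_control]
threshold:
  type: fixed
  value: 0.5
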