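# demo study configuration: a small synthetic cohort run end to end
seed: 42
cohort:
  n_subjects: 1200
  p_advanced: 0.505
  p_cae_high_given_AA: 0.318
  p_cae_high_given_nAA: 0.103
  baseline_hazard: 0.003
profiles:
  enabled: true
  bin_width: 2.0e6
  noise_sd: 0.1
classification:
  gain_threshold: 0.1
  loss_threshold: -0.1
  min_fraction: 0.5
matching:
  M: 2
  age_window: 5
  reuse_policy: without_replacement
  shortfall_policy: drop
  control_policy: never_cases
design:
  planned_p_case: 0.32
  planned_p_ctrl: 0.13
  simulate: true
  reps: 2000
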