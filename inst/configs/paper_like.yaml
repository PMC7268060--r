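# Emulates the emulated study's cohort at the trajectory level:
# 22 subjects, nominally 17 sessions of 165 trials, alpha band,
# rejection thresholds at their protocol values.
source: synthetic
signal: erd
seed: 1
erd_method: trialwise
reml: true
cohort:
  n_subjects: 22
  sessions_per_subject: 17
  session_jitter_sd: 1.8
  trials_per_session: 165
  trial_jitter_sd: 19.5
  fs: 500
  beta0: -30.0
  beta1: -0.5
  sd_b0: 10.0
  sd_b1: 0.4
  rho_b: 0.0
  sigma_eps: 8.0
  gamma: [2.0, 0.05, -4.0, -0.15]
  sigma_out: 3.0
  seed: 1
rejection:
  hf_band: [110, 140]
  hf_z_threshold: 4
  offset_z_threshold: 20
  emg_wl_sd_threshold: 3
  min_trials_per_session: 16
  min_fraction: 0.10
  max_removed_sessions_fraction: 0.5
  eog_component_corr_threshold: 0.7
bands:
  - name: alpha
    f_lo: 8
    f_hi: 12
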