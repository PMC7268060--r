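# Small cohort with full multichannel signal synthesis: exercises the whole
# chain (epoching -> artifact rejection -> ERD -> two-stage model) at desk
# scale.
source: synthetic
signal: raw
seed: 7
cohort:
  n_subjects: 6
  sessions_per_subject: 3
  session_jitter_sd: 0
  trials_per_session: 60
  trial_jitter_sd: 0
  fs: 500
  beta0: -30.0
  beta1: -1.5
  sd_b0: 8.0
  sd_b1: 0.5
  sigma_eps: 4.0
  gamma: [2.0, 0.05, -4.0, -0.15]
  sigma_out: 1.0
  artifact_rates:
    eog: 0.05
    hf: 0.05
    offset: 0.02
    emg: 0.05
  seed: 7
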