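# Stock study configuration: calibrated population radiosensitivity,
# fixed kinetics, slow resensitization, the two clinical HDR regimens and
# their hypothetical 7-day-interval shortenings.
population:
  mean_alpha0: 0.12      # Gy^-1
  sd_alpha0: 0.02
  mean_alpha_m: 0.23     # Gy^-1
  sd_alpha_m: 0.02
  mean_beta0: 0.026666666666666668   # mean_alpha0 / 4.5, Gy^-2
  sd_beta0: 0.01
  ab_window: [3.5, 6.0]  # Gy, acceptance bounds on time-mean alpha/beta
kinetics:
  n0: 1.0e+08             # clonogens
  lambda: 0.02           # day^-1, slow repopulation (prostate)
b: 0.066                 # day^-2, resensitization rate
schedules:
  2F/14d: {times_days: [0, 14], doses_gy: [14, 14]}
  3F/28d: {times_days: [0, 14, 28], doses_gy: [11, 11, 11]}
  2F/7d:  {times_days: [0, 7], doses_gy: [14, 14]}
  3F/14d: {times_days: [0, 7, 14], doses_gy: [11, 11, 11]}
cohorts:
  - {schedule: 3F/28d, n_patients: 107, clinical_failures: 5, seed_offset: 101}
  - {schedule: 2F/14d, n_patients: 103, clinical_failures: 15, seed_offset: 202}
n_samples: 10000
seed: 20210929
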