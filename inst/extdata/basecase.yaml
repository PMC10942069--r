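clinical:
  hr_dfs: 0.76
  hr_lrr: 0.58
  hr_met: 0.48
  p_lrr_base: 0.0294
  p_met_base: 0.0785
  p_dfs_after_lrr: 0.1
  rr_met_after_lrr: 3.64
  p_chf_trast: 0.198
  p_chf_chemo: 0.007
  p_death_met: 0.295
  p_lrr_chf: 0.0294
  p_met_chf: 0.0785
utilities:
  u_dfs: 0.832
  u_lrr: 0.828
  u_dfs_post_lrr: 0.789
  u_dfs_chf: 0.67
  u_met: 0.762
costs:
  trast_drug: 787384650.0
  her2_detection: 686116.0
  trast_other_direct_medical: 27040970.0
  trast_direct_nonmedical: 5724180.0
  paclitaxel_treatment: 32116418.0
  c_dfs: 1400846.0
  c_lrr: 216688208.0
  c_dfs_post_lrr: 1400846.0
  c_met: 131065482.0
  c_dfs_chf: 9529840.0
  p_440: 45596775.0
  p_150: 15550710.0
  trast_drug_sharing: 570022437.0
  paclitaxel_drug_only: 32116418.0
settings:
  start_age: 50.0
  patient_weight: 52.899999999999999
  cohort_size: 5052.0
  max_age: 100.0
  cycle_length: 1.0
  discount_rate: 0.03
  benefit_duration: 5.0
  recurrence_cutoff: 20.0
  half_cycle_correction: no
  hr_method: rate
  drug_cost_mode: printed
  exchange_rate: 22745.0
  wtp_thresholds:
  - 83000000.0
  - 249000000.0
  dose_loading: 8.0
  dose_maintenance: 6.0
  dose_interval_weeks: 3.0
  dose_duration_weeks: 52.0
psa:
  n_iterations: 10000.0
  rel_range: 0.1
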