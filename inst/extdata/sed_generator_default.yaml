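n_participants: 2944
seed: 1
random_intercept_sd: 0.5
cross_correlation:
  within_mental: 0.40000000000000002
  within_physical: 0.40000000000000002
  across: 0.20000000000000001
scales:
- name: fine_motor
  mdc90: 8.19999999999999929
  baseline_mean: 43.0
  baseline_sd: 5.59999999999999964
  change_mean_by_wave:
  - -0.5
  - 0.40000000000000002
  - 0.0
  change_sd_by_wave:
  - 5.59999999999999964
  - 5.5
  - 5.20000000000000018
  baseline_change_cor: -0.34999999999999998
- name: upper_body
  mdc90: 4.59999999999999964
  baseline_mean: 39.39999999999999858
  baseline_sd: 5.79999999999999982
  change_mean_by_wave:
  - -0.20000000000000001
  - 0.29999999999999999
  - 0.20000000000000001
  change_sd_by_wave:
  - 4.79999999999999982
  - 5.0
  - 4.70000000000000018
  baseline_change_cor: -0.34999999999999998
- name: comm_cog
  mdc90: 7.09999999999999964
  baseline_mean: 41.79999999999999716
  baseline_sd: 6.59999999999999964
  change_mean_by_wave:
  - 0.69999999999999996
  - 0.69999999999999996
  - 0.5
  change_sd_by_wave:
  - 6.70000000000000018
  - 7.0
  - 7.09999999999999964
  baseline_change_cor: -0.34999999999999998
- name: basic_mobility
  mdc90: 4.70000000000000018
  baseline_mean: 40.20000000000000284
  baseline_sd: 6.0
  change_mean_by_wave:
  - 0.29999999999999999
  - 0.10000000000000001
  - 0.10000000000000001
  change_sd_by_wave:
  - 4.79999999999999982
  - 4.90000000000000036
  - 4.5
  baseline_change_cor: -0.34999999999999998
- name: resilience
  mdc90: 8.19999999999999929
  baseline_mean: 47.60000000000000142
  baseline_sd: 9.59999999999999964
  change_mean_by_wave:
  - 0.20000000000000001
  - 1.19999999999999996
  - 0.5
  change_sd_by_wave:
  - 10.09999999999999964
  - 10.09999999999999964
  - 10.30000000000000071
  baseline_change_cor: -0.34999999999999998
- name: interpersonal
  mdc90: 8.59999999999999964
  baseline_mean: 44.39999999999999858
  baseline_sd: 8.80000000000000071
  change_mean_by_wave:
  - 2.10000000000000009
  - 1.30000000000000004
  - 1.0
  change_sd_by_wave:
  - 10.59999999999999964
  - 12.19999999999999929
  - 12.09999999999999964
  baseline_change_cor: -0.34999999999999998
- name: mood
  mdc90: 10.59999999999999964
  baseline_mean: 38.60000000000000142
  baseline_sd: 12.0
  change_mean_by_wave:
  - 4.0
  - 1.30000000000000004
  - 1.0
  change_sd_by_wave:
  - 12.90000000000000036
  - 13.5
  - 12.69999999999999929
  baseline_change_cor: -0.34999999999999998
medical:
- name: csi
  family: truncnorm
  wave_means:
  - 25.19999999999999929
  - 22.19999999999999929
  - 20.39999999999999858
  - 19.19999999999999929
  wave_sds:
  - 11.19999999999999929
  - 12.69999999999999929
  - 12.69999999999999929
  - 12.5
  floor: 0.0
  wave_cor: 0.63921494188226469
- name: bmi
  family: truncnorm
  wave_means:
  - 31.10000000000000142
  - 31.5
  - 31.60000000000000142
  - 32.20000000000000284
  wave_sds:
  - 8.90000000000000036
  - 8.59999999999999964
  - 8.5
  - 8.80000000000000071
  floor: 12.0
  wave_cor: 0.92502544310595469
- name: inpatient_admissions
  family: count
  wave_means:
  - 0.5
  - 0.29999999999999999
  - 0.20000000000000001
  - 0.20000000000000001
  wave_sds:
  - 0.90000000000000002
  - 0.80000000000000004
  - 0.80000000000000004
  - 0.59999999999999998
  floor: 0.0
  wave_cor: 0.41589506172839502
- name: dast
  family: count
  wave_means:
  - 1.10000000000000009
  - 0.69999999999999996
  - 0.59999999999999998
  - 0.59999999999999998
  wave_sds:
  - 2.0
  - 1.60000000000000009
  - 1.5
  - 1.60000000000000009
  floor: 0.0
  wave_cor: 0.583125
- name: audit
  family: count
  wave_means:
  - 3.5
  - 2.70000000000000018
  - 2.5
  - 2.5
  wave_sds:
  - 5.70000000000000018
  - 5.79999999999999982
  - 4.59999999999999964
  - 4.59999999999999964
  floor: 0.0
  wave_cor: 0.6588197129505422
- name: er_visits
  family: count
  wave_means:
  - 1.19999999999999996
  - 0.88
  - 0.70999999999999996
  - 0.58999999999999997
  wave_sds:
  - 1.89999999999999991
  - 1.60000000000000009
  - 1.5
  - 1.30000000000000004
  floor: 0.0
  wave_cor: 0.47753879892037787
demographics:
  work_history:
    worked_past_2yr: 0.45000000000000001
    no_recent_work: 0.55000000000000004
  education:
    hs: 0.40000000000000002
    less_hs: 0.25
    some_college: 0.20000000000000001
    bachelor: 0.14999999999999999
  housing:
    stable: 0.69999999999999996
    unstable: 0.29999999999999999
  vehicle_access:
    'no': 0.55000000000000004
    'yes': 0.45000000000000001
  race:
    white: 0.5
    black: 0.29999999999999999
    other: 0.20000000000000001
  arm:
    usual: 0.33333333333333331
    basic: 0.33333333333333331
    full: 0.33333333333333331
  age_mean: 38.0
  age_sd: 8.0
  age_range:
  - 18.0
  - 49.0
missingness:
  block_pattern_probs:
    '0': 0.55000000000000004
    '7': 0.20000000000000001
    '14': 0.14999999999999999
    '21': 0.10000000000000001
  drive_presence_by_wave:
  - 0.51000000000000001
  - 0.35999999999999999
  - 0.38
  - 0.35999999999999999
  ride_presence_by_wave:
  - 0.31
  - 0.22
  - 0.17000000000000001
  - 0.13
  wheelchair_presence_by_wave:
  - 0.04
  - 0.03
  - 0.03
  - 0.03
true_coefficients:
  intercept_wave1: -2.45095139936329209
  intercept_wave2: -2.17736651326237629
  intercept_wave3: -2.30525594343642437
  work_history:worked_past_2yr: 0.59999999999999998
  education:bachelor: 0.25
  race:other: 0.20000000000000001
  arm:basic: 0.14999999999999999
  arm:full: 0.14999999999999999
  comm_cog_change: 0.29999999999999999
  upper_body_change: 0.20000000000000001
  resilience_change: 0.14999999999999999
  upper_body_baseline: 0.14999999999999999
  has_drive: 0.29999999999999999
  bmi_change: 0.14999999999999999
  er_visits_baseline: -0.10000000000000001
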