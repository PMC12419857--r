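# Default synthetic-cohort calibration, version 1.
# Biomarker means/SDs echo a large mid-life UK cohort; PhenoAge-relevant
# markers are emitted directly in the scoring coefficients' training units
# (albumin g/L, creatinine umol/L, glucose mmol/L, CRP mg/dL, lymphocyte %,
# MCV fL, RDW %, ALP U/L, WBC 10^9/L), so the default unit map is identity.
# Transition intensities are calibrated so the baseline state mix is about
# 18% none / 55% single / 23% dual / 3% triple and overall mortality over
# the default follow-up is about 8%.
n_participants: 1000
seed: 1
age_range: [37.0, 73.0]
age_mean: 56.4
age_sd: 8.1
sex_ratio: 0.54
progression_start_age: 25.0
followup_years: 13.6
frailty_sd: 1.0
gompertz_mortality:
  rate_intercept: 0.0
  age_slope: 0.09
  reference_age: 60.0

biomarker_models:
  sbp:        {intercept: 111.4,  age_slope: 0.50,   sex_offset: -4.0,  residual_sd: 18.0,  frailty_loading: 0.30, unit: mmHg}
  fev1:       {intercept: 4.51,   age_slope: -0.030, sex_offset: -0.70, residual_sd: 0.55,  frailty_loading: -0.30, unit: L}
  cholesterol: {intercept: 198.1, age_slope: 0.40,   sex_offset: 4.0,   residual_sd: 43.0,  frailty_loading: 0.10, unit: mg/dL}
  hba1c:      {intercept: 4.76,   age_slope: 0.012,  sex_offset: -0.05, residual_sd: 0.55,  frailty_loading: 0.35, unit: percent}
  urea:       {intercept: 11.7,   age_slope: 0.060,  sex_offset: -1.0,  residual_sd: 3.7,   frailty_loading: 0.20, unit: mg/dL}
  crp:        {intercept: -2.35,  age_slope: 0.015,  sex_offset: 0.10,  residual_sd: 1.00,  frailty_loading: 0.40, unit: mg/dL, log_scale: true}
  alp:        {intercept: 66.3,   age_slope: 0.30,   sex_offset: 2.0,   residual_sd: 25.0,  frailty_loading: 0.25, unit: U/L}
  albumin:    {intercept: 49.8,   age_slope: -0.080, sex_offset: -0.50, residual_sd: 2.5,   frailty_loading: -0.30, unit: g/L}
  creatinine: {intercept: 63.5,   age_slope: 0.150,  sex_offset: -13.0, residual_sd: 12.0,  frailty_loading: 0.25, unit: umol/L}
  lymph_pct:  {intercept: 33.5,   age_slope: -0.080, sex_offset: 0.50,  residual_sd: 7.3,   frailty_loading: -0.15, unit: percent}
  mcv:        {intercept: 80.0,   age_slope: 0.050,  sex_offset: -0.30, residual_sd: 5.2,   frailty_loading: 0.10, unit: fL}
  glucose:    {intercept: 4.26,   age_slope: 0.015,  sex_offset: -0.10, residual_sd: 1.10,  frailty_loading: 0.35, unit: mmol/L}
  rdw:        {intercept: 12.3,   age_slope: 0.020,  sex_offset: 0.00,  residual_sd: 0.95,  frailty_loading: 0.30, unit: percent}
  wbc:        {intercept: 6.30,   age_slope: 0.010,  sex_offset: 0.10,  residual_sd: 1.90,  frailty_loading: 0.25, unit: 1e9/L}

transition_log_intensities:
  none_single: -2.84
  single_dual: -3.99
  dual_triple: -4.75
  single_death: -5.92
  dual_death: -5.23
  triple_death: -4.54
transition_frailty_loghr:
  none_single: 0.25
  single_dual: 0.25
  dual_triple: 0.25
  single_death: 0.35
  dual_death: 0.35
  triple_death: 0.35

covariate_models:
  ethnicity: {levels: [white, other], probs: [0.945, 0.055]}
  education:
    levels: [degree, a_level, gcse, other]
    probs: [0.33, 0.11, 0.27, 0.29]
    ordered: true
  income:
    levels: [lt_18k, 18_31k, 31_52k, 52_100k, gt_100k]
    probs: [0.22, 0.25, 0.26, 0.21, 0.06]
    ordered: true
  smoking: {levels: [never, ever], probs: [0.55, 0.45]}
  alcohol: {levels: [never, ever], probs: [0.08, 0.92]}
  bmi_category: {levels: [normal, overweight, obese], probs: [0.34, 0.43, 0.23]}
  townsend: {mean: -1.37, sd: 3.04}
  physical_activity: {shape: 1.0, scale: 2660.0}
  diet_score: {prob: 0.45}
  no2: {mean: 26.6, sd: 7.6}
  nox: {mean: 43.9, sd: 15.5}
  pm25: {mean: 9.98, sd: 1.05}
  pm10: {mean: 16.2, sd: 1.9}

missingness_mechanism: mcar
missingness_rates:
  income: 0.14
  education: 0.011
  townsend: 0.012
  physical_activity: 0.22
  diet_score: 0.08
  smoking: 0.005
  alcohol: 0.002
  bmi_category: 0.02
  ethnicity: 0.005
  no2: 0.013
  nox: 0.013
  pm25: 0.049
  pm10: 0.049
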