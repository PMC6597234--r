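population:
  'n': 10000.0
  frac_high_risk: 0.2
  table: ~
  family_history_prev: 0.15
  height_mean: 1.65
  height_sd: 0.07
  weight_init:
    age_breaks:
    - 0.0
    - 25.0
    - 35.0
    - .inf
    standard:
    - - 0.78
      - 0.16
      - 0.06
    - - 0.68
      - 0.22
      - 0.1
    - - 0.62
      - 0.26
      - 0.12
    high_risk_ethnicity:
    - - 0.7
      - 0.2
      - 0.1
    - - 0.58
      - 0.27
      - 0.15
    - - 0.52
      - 0.3
      - 0.18
simulation:
  calendar_start_year: 1988.0
  horizon_years: 29.0
  burn_in_years: 20.0
  dt_months: 1.0
  seed: 1.0
  bud_scope: all_reproductive
  female_fraction: 0.493
  postpartum_weeks: 26.0
etiology: mechanistic
physiology:
  bmi_ref: 25.0
  k_bmi: 0.05
  s_min: 0.1
  rho_preg: 0.5
  g_thr: 1.5
  g_igr: 1.5
  g_dm: 2.0
  g_gdm: 1.3
  g_max: 10.0
  k_decay: 0.2
  r_regen: 0.05
  e_rev: 1.0
  bmi_secular: 0.05
  bmi_drift_age:
    age:
    - 15.0
    - 25.0
    - 35.0
    - 45.0
    - 55.0
    - 65.0
    - 80.0
    rate:
    - 0.15
    - 0.1
    - 0.06
    - 0.03
    - 0.0
    - -0.05
    - -0.1
  childhood_rate: 0.5
  bmi_noise_sd: 0.25
  gwg_mean: 12.0
  gwg_sd: 3.0
  retention_frac: 0.3
  phenotype_mix:
  - 0.333333333333333
  - 0.333333333333333
  - 0.333333333333333
  base_high: 0.97
  base_high_sd: 0.02
  base_low: 0.85
  base_low_sd: 0.05
  base_mixed: 0.9
  base_mixed_sd: 0.04
fertility:
  age_lo:
  - 15.0
  - 20.0
  - 25.0
  - 30.0
  - 35.0
  - 40.0
  - 45.0
  age_hi:
  - 20.0
  - 25.0
  - 30.0
  - 35.0
  - 40.0
  - 45.0
  - 50.0
  rate:
  - 0.015
  - 0.055
  - 0.1
  - 0.12
  - 0.07
  - 0.015
  - 0.002
mortality:
  exit_rate:
  - 0.004
  - 0.002
  - 0.002
  - 0.003
  - 0.004
  - 0.004
  - 0.004
  - 0.004
  - 0.004
  - 0.005
  - 0.006
  - 0.009
  - 0.014
  - 0.022
  - 0.036
  - 0.06
  - 0.1
  - 0.18
screening:
  mode: universal
  universal_week: 26.0
  early_week: 12.0
  participation: 0.95
diagnostics:
  years:
  - 1988.0
  - 2014.0
  thresholds:
  - 4.2
  - 2.8
treatment:
  m_full: 0.8
  ramp_weeks: 4.0
  pharmaco_g: 2.6
outcomes:
  p_min: 0.05
  p_max: 0.45
  k: 4.0
  g_mid: 1.8
endowment:
  b_base_mult: 0.9
  drift_mult: 1.3
risk_count:
  p0: 0.03
  beta: 0.04
costs:
  booking: 40.0
  early_screen: 60.0
  ogtt: 60.0
  diagnosis: 0.0
  lifestyle_rx: 250.0
  pharmaco_rx: 400.0
  delivery_care: 3000.0
  postpartum_test: 60.0
interventions:
- name: highrisk_interpregnancy
  target: high_risk
  timing: inter_pregnancy
  uptake: 0.6
  bmi_effect_kg: -5.0
  s_multiplier: 1.1
  duration_years: 5.0
  adherence_decay: 0.5
  start_year: 2009.0
  end_year: 2016.0
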