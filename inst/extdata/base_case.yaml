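timing:
  sleep_minutes: 480.0
  wake_to_hospital_minutes: 51.0
  door_to_needle_minutes: 77.0
  mri_additional_minutes: 30.0
  stochastic_delays: no
  delay_distribution_family: fixed
onset:
  family: uniform
  alpha: 1.0
  beta: 1.0
diagnostic:
  sensitivity: 0.62
  specificity: 0.78
  eligibility_threshold_minutes: 270.0
treatment_effect:
  band_edges_minutes:
  - 180.0
  - 270.0
  - 360.0
  odds_ratios:
  - 1.75
  - 1.26
  - 1.0
  beyond_last_band_or: 1.0
progression:
  nonstroke_death_hr_by_mrs:
  - 1.0
  - 1.0
  - 1.11
  - 1.27
  - 1.71
  - 2.37
  annual_recurrent_stroke_prob: 0.051
  recurrent_stroke_case_fatality: 0.19
costs:
  mri: 488.0
  acute_hosp_no_treatment: 11462.0
  acute_hosp_with_treatment: 18182.0
  annual_mrs0_3: 5293.0
  annual_mrs4_5: 13557.0
  recurrent_stroke_hosp: 20079.0
utilities:
  by_mrs:
  - 0.8
  - 0.8
  - 0.65
  - 0.5
  - 0.35
  - 0.2
demographics:
  start_age: 65.0
  male_fraction: 0.6
  annual_discount_rate: 0.03
  willingness_to_pay: 100000.0
  max_age: 110.0
population_impact:
  wakeup_share_of_ischemic_strokes: 0.2
  sich_rate_among_treated: 0.055
mrs_dist:
  mrs:
  - 0
  - 1
  - 2
  - 3
  - 4
  - 5
  - 6
  untreated:
  - 0.2706
  - 0.1804
  - 0.183
  - 0.1464
  - 0.1098
  - 0.0732
  - 0.0366
  treated:
  - 0.2706
  - 0.1804
  - 0.183
  - 0.1464
  - 0.1098
  - 0.0732
  - 0.0366
life_table:
  source: makeham
  a: 0.0002
  b: 3.0e-05
  c: 1.1
  male_multiplier: 1.0
  female_multiplier: 1.0
simulation:
  'n': 100000.0
  seed: 1.0
  cycle_accrual: full

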