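# Default synthetic parameter fixture for the nnsbia budget-impact
# model. This is a calibrated stand-in, not a transcription of any
# source dataset: values noted 'calibrated'/'back-solved' were solved
# by make_default_fixture(); the rest are documented assumptions.

meta:
  label: default synthetic fixture (calibrated stand-in)
  currency_year: 2024.0
parameters:
- name: n_patients
  value: 100.0
  kind: count
  owsa: no
  note: modelled cohort size
  uncertainty_frac: 0.0
- name: prop_gab_25_28
  value: 0.5
  kind: probability
  owsa: yes
  note: share of the cohort in the younger GAB stratum
- name: prop_nns_at_birth
  value: 0.02
  kind: probability
  owsa: yes
  note: NNS already developed at birth; small for GAB 25-30
- name: prop_fof_fail_pfos
  value: 0.070058554187
  kind: probability
  owsa: yes
  note: 'calibrated: NGT discharges per 100 near 6.4'
- name: prop_fof_fail_soc
  value: 0.065455786708
  kind: probability
  owsa: yes
  note: 'calibrated: NGT discharges per 100 near 5.9'
- name: training_start_day
  value: 21.0
  kind: count
  owsa: yes
  note: day NNS training begins (infant stable, ~32 wk PMA)
  upper: 179.0
- name: time_to_fof_soc
  value: 48.520051973376
  kind: count
  owsa: yes
  note: 'calibrated: comparator mean NICU LOS 65.8 d'
  lower: 1.0
  upper: 100000.0
- name: time_to_fof_ratio_pfos
  value: 0.860310723309
  kind: factor
  owsa: yes
  note: 'calibrated: intervention mean NICU LOS 59.8 d'
  lower: 0.05
  upper: 3.0
- name: ttd
  value: 0.8
  kind: factor
  owsa: yes
  note: time-to-discharge factor for the non-FOF group
  lower: 0.01
  upper: 2.0
- name: prop_discharge_to_ward
  value: 0.15
  kind: probability
  owsa: yes
  note: share discharged via a lower-acuity ward
- name: ward_los_mean_days
  value: 5.0
  kind: count
  owsa: yes
  note: assumption
  lower: 1.0
  upper: 60.0
- name: rehosp_los_mean_days
  value: 8.0
  kind: count
  owsa: yes
  note: assumption
  lower: 1.0
  upper: 60.0
- name: mort_hospital_daily
  value: 0.0012
  kind: probability
  owsa: yes
  note: ~7.5% in-hospital mortality over a 66-day stay
  period_days: 1.0
- name: mort_home_annual_y1
  value: 0.01
  kind: probability
  owsa: yes
  note: assumption
  period_days: 365.0
- name: mort_home_annual_later
  value: 0.002
  kind: probability
  owsa: yes
  note: assumption
  period_days: 365.0
- name: p_infection_hospital_daily
  value: 0.0012
  kind: probability
  owsa: yes
  note: tube infections per hospital day
  period_days: 1.0
- name: p_infection_home_annual
  value: 0.095
  kind: probability
  owsa: yes
  note: assumption
  period_days: 365.0
- name: or_infection_ngt_home
  value: 2.0
  kind: odds_ratio
  owsa: yes
  note: home infection odds, NGT carriers vs FOF achievers
- name: rehosp_rate_gab_24_27
  value: 0.66
  kind: rate
  owsa: yes
  note: first-year rehospitalisation rate, younger stratum
  period_days: 365.0
- name: rehosp_rate_gab_28_31
  value: 0.42
  kind: rate
  owsa: yes
  note: first-year rehospitalisation rate, older stratum
  period_days: 365.0
- name: rehosp_year_mult_y2
  value: 0.65
  kind: factor
  owsa: yes
  note: assumption
  lower: 0.0
  upper: 1.5
- name: rehosp_year_mult_y3
  value: 0.5
  kind: factor
  owsa: yes
  note: assumption
  lower: 0.0
  upper: 1.5
- name: rehosp_year_mult_y4
  value: 0.35
  kind: factor
  owsa: yes
  note: assumption
  lower: 0.0
  upper: 1.5
- name: rehosp_year_mult_y5
  value: 0.27
  kind: factor
  owsa: yes
  note: assumption
  lower: 0.0
  upper: 1.5
- name: nicu_charge_per_day
  value: 3371.65379556367
  kind: charge
  owsa: yes
  note: 'back-solved: comparator payer total matches the published magnitude'
- name: ward_charge_per_day
  value: 1300.0
  kind: charge
  owsa: yes
  note: lower-acuity/level-I ward priced like a general ward
- name: infection_hospital_charge_per_event
  value: 2260.0
  kind: charge
  owsa: yes
  note: assumption
- name: ngt_discharge_charge_per_event
  value: 3850.0
  kind: charge
  owsa: yes
  note: tube supplies, home-nursing setup and follow-up
- name: infection_home_cost_per_event
  value: 1050.0
  kind: cost
  owsa: yes
  note: assumption
- name: rehosp_cost_per_event
  value: 12937.0
  kind: cost
  owsa: yes
  note: per-admission cost, valued in 2022 USD and inflated on load
  year_of_value: 2022.0
- name: cost_to_charge_ratio
  value: 0.433
  kind: factor
  owsa: yes
  note: scalar hospital cost-to-charge ratio
  uncertainty_frac: 0.1
  lower: 0.05
  upper: 1.0
- name: staff_wage_per_hour
  value: 50.0
  kind: cost
  owsa: yes
  note: assumption
- name: staff_sessions_per_patient
  value: 63.0
  kind: count
  owsa: yes
  note: 3 sessions/day over a 21-day training course
- name: staff_minutes_per_session_pfos
  value: 12.0
  kind: count
  owsa: yes
  note: device supervision needs less hands-on time
- name: staff_minutes_per_session_soc
  value: 15.0
  kind: count
  owsa: yes
  note: assumption
- name: prop_women_reproductive_age
  value: 0.253
  kind: probability
  owsa: yes
  note: women 15-44 among covered lives
- name: fertility_rate_annual
  value: 0.0565
  kind: rate
  owsa: yes
  note: births per woman of reproductive age per year
  period_days: 365.0
- name: prop_preterm_25_30
  value: 0.007118194658
  kind: probability
  owsa: yes
  note: back-solved so covered lives = 982,791
- name: time_to_fof_soc_gab_25_28
  value: 66.289308950105
  kind: count
  owsa: yes
  note: 'calibrated: subgroup comparator LOS 81.2 d'
  lower: 1.0
  upper: 1000.0
- name: time_to_fof_ratio_pfos_gab_25_28
  value: 0.977627739876
  kind: factor
  owsa: yes
  note: 'calibrated: subgroup intervention LOS 80.0 d'
  lower: 0.05
  upper: 3.0
- name: time_to_fof_soc_gab_29_30
  value: 31.452005017414
  kind: count
  owsa: yes
  note: 'calibrated: subgroup comparator LOS 50.4 d'
  lower: 1.0
  upper: 1000.0
- name: time_to_fof_ratio_pfos_gab_29_30
  value: 0.631318995082
  kind: factor
  owsa: yes
  note: 'calibrated: subgroup intervention LOS 39.6 d'
  lower: 0.05
  upper: 3.0

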