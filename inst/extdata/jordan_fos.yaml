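treatments:
  BRV:
    transition:
      p:
        seizure_free: 0.065
        partial_response: 0.355
        non_response: 0.37
        discontinued: 0.21
      se:
        seizure_free: 0.003
        partial_response: 0.018
        non_response: 0.011
        discontinued: 0.011
    ae_annual:
      ataxia: 0.03
      dizziness: 0.13
      fatigue: 0.11
      nausea: 0.05
      somnolence: 0.14
    dose:
      titration: 50.0
      maintenance: 100.0
    drug_cost_per_mg:
      mean: 0.042
      se: 0.016
  ESL:
    transition:
      p:
        seizure_free: 0.032
        partial_response: 0.33
        non_response: 0.469
        discontinued: 0.169
      se:
        seizure_free: 0.002
        partial_response: 0.017
        non_response: 0.009
        discontinued: 0.009
    ae_annual:
      ataxia: 0.06
      dizziness: 0.23
      fatigue: 0.06
      nausea: 0.12
      somnolence: 0.12
    dose:
      titration: 400.0
      maintenance: 800.0
    drug_cost_per_mg:
      mean: 0.004
      se: 0.004
  LCM:
    transition:
      p:
        seizure_free: 0.03
        partial_response: 0.308
        non_response: 0.448
        discontinued: 0.214
      se:
        seizure_free: 0.002
        partial_response: 0.016
        non_response: 0.011
        discontinued: 0.011
    ae_annual:
      ataxia: 0.08
      dizziness: 0.24
      fatigue: 0.06
      nausea: 0.11
      somnolence: 0.1
    dose:
      titration: 100.0
      maintenance: 400.0
    drug_cost_per_mg:
      mean: 0.013
      se: 0.003
  PER:
    transition:
      p:
        seizure_free: 0.035
        partial_response: 0.296
        non_response: 0.493
        discontinued: 0.176
      se:
        seizure_free: 0.002
        partial_response: 0.015
        non_response: 0.009
        discontinued: 0.009
    ae_annual:
      ataxia: 0.04
      dizziness: 0.23
      fatigue: 0.07
      nausea: 0.01
      somnolence: 0.14
    dose:
      titration: 2.0
      maintenance: 8.0
    drug_cost_per_mg:
      mean: 0.804
      se: 0.267
reference: BRV
services:
  inpatient_night: 100.0
  emergency_visit: 30.0
  neurologist_visit: 14.0
  gp_visit: 8.0
  eeg: 100.0
ae_drug_cost_per_mg:
  acetazolamide:
    mean: 0.001
    se: 0.001
  cinnarizine:
    mean: 0.001
    se: 0.001
ae_management:
  ataxia:
    drug: acetazolamide
    daily_dose_mg: 250.0
    days: 90.0
    gp_visits: 1.0
  dizziness:
    drug: cinnarizine
    daily_dose_mg: 50.0
    days: 90.0
    gp_visits: 1.0
  fatigue:
    drug: .na.character
    daily_dose_mg: 0.0
    days: 0.0
    gp_visits: 1.0
  nausea:
    drug: cinnarizine
    daily_dose_mg: 50.0
    days: 90.0
    gp_visits: 1.0
  somnolence:
    drug: .na.character
    daily_dose_mg: 0.0
    days: 0.0
    gp_visits: 1.0
state_bundles:
  seizure_free:
    neurologist_visit: 1.0
    eeg: 1.0
  partial_response:
    neurologist_visit: 1.0
    eeg: 1.0
  non_response:
    emergency_visit: 1.0
    inpatient_night: 1.0
    neurologist_visit: 1.0
    eeg: 1.0
  discontinued:
    neurologist_visit: 1.0
model:
  n_cycles: 8
  cycle_length_days: 90.0
  variant: absorbing_sf_disc
  effect: ever_sf
discount:
  annual_rate: 0.035
  psa_low: 0.0
  psa_high: 0.05
  psa_se: 0.00625
cost_variation_pct: 0.25
ae_prob_variation_pct: 0.25
ae_accrual: all_cycles
psa:
  n_iterations: 2000
  seed: 20250101
wtp: 9000.0
wtp_grid:
- 0.0
- 500.0
- 1000.0
- 1500.0
- 2000.0
- 2500.0
- 3000.0
- 3500.0
- 4000.0
- 4500.0
- 5000.0
- 5500.0
- 6000.0
- 6500.0
- 7000.0
- 7500.0
- 8000.0
- 8500.0
- 9000.0
- 9500.0
- 10000.0
- 10500.0
- 11000.0
- 11500.0
- 12000.0
- 12500.0
- 13000.0
- 13500.0
- 14000.0
- 14500.0
- 15000.0
- 15500.0
- 16000.0
- 16500.0
- 17000.0
- 17500.0
- 18000.0
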