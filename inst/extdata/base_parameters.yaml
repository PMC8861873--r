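meta:
  schema_version: '1.0'
  currency: EUR-2021
  note: DTC app reimbursement price carried at 239.96, the only value consistent with
    the 475.08 first-treatment-cycle state cost; alternative published figures (296/296.99)
    refer to a later price level and are not used.
settings:
  cohort_size: 10000
  start:
    LOW: 5320
    HIGH: 1120
    REMISSION: 3560
  discount_rate: 0.03
  cycles_per_year: 12
  horizon_years: 3
transitions:
  low_row:
    LOW: 0.16
    HIGH: 0.01
    REMISSION: 0.03
  low_to_treatment: 0.75
  high_row:
    LOW: 0.02
    HIGH: 0.08
  high_to_treatment: 0.8
  treatment_rows:
    DTC:
      w1_4:
        LOW: 0.0514
        HIGH: 0.0111
        CONTINUE: 0.875
        REMISSION: 0.0625
      w4_8:
        LOW: 0.0514
        HIGH: 0.0111
        CONTINUE: 0.875
        REMISSION: 0.0625
    TAU:
      w1_4:
        LOW: 0.0267
        HIGH: 0.0058
        CONTINUE: 0.935
        REMISSION: 0.0325
      w4_8:
        LOW: 0.0177
        HIGH: 0.0038
        CONTINUE: 0.957
        REMISSION: 0.0215
  attrition:
    DTC:
    - 0.125
    - 0.125
    TAU:
    - 0.065
    - 0.043
  remission_share: 0.5
  low_trajectory_share: 0.822
  end_row:
    LOW: 0.235
    HIGH: 0.051
    REMISSION: 0.614
  end_to_healthy:
    DTC: 0.1
    TAU: 0.05
  remission_row:
    LOW: 0.505
    HIGH: 0.109
    REMISSION: 0.386
utilities:
  DTC:
    LOW: 0.655
    HIGH: 0.61
    T_W1_4: 0.655
    T_W4_8: 0.699
    T_W8_12: 0.748
    REMISSION: 0.806
    HEALTHY: 0.806
  TAU:
    LOW: 0.655
    HIGH: 0.61
    T_W1_4: 0.655
    T_W4_8: 0.717
    T_W8_12: 0.729
    REMISSION: 0.806
    HEALTHY: 0.806
unit_costs:
  app_price: 239.96
  gp_consultation: 20.47
  specialist_consultation: 21.36
  physio_session: 21.11
  physio_sessions: 6
  prescription_charge: 10
  copay_rate: 0.1
  pharmacotherapy: 16.81
  diagnostics: 29.24
  monthly_gross_wage: 3092
  working_days_per_month: 21
state_costs:
  DTC:
    LOW: 441.72
    HIGH: 588.96
    T_W1_4: 475.08
    T_W4_8: 16.81
    T_W8_12: 16.81
    REMISSION: 0
    HEALTHY: 0
  TAU:
    LOW: 441.72
    HIGH: 588.96
    T_W1_4: 377.85
    T_W4_8: 16.81
    T_W8_12: 16.81
    REMISSION: 0
    HEALTHY: 0
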