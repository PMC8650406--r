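transitions:
  tpA2B_ect: 0.696
  tpA2B_esk: 0.392
  tpB2C_ect: 0.108
  tpB2C_mect: 0.03
  tpB2C_esk: 0.0724
  tpD2E: 0.107
  tpE2D: 0.232
  tpDep2G: 0.00304
  remission_mortality:
    '45': 0.00018
    '50': 0.000265
    '55': 0.000407
    '60': 0.000646
    '65': 0.001
    '70': 0.00163
    '75': 0.00285
utilities:
  annual_remission: 0.81
  annual_depression: 0.57
  use_rounded_cycle: no
wages:
  fulltime_wage: 2340.0
  parttime_wage: 680.0
  payroll_tax_rate: 0.12
  payroll_band_low: 702.009999999999991
  payroll_band_high: 3863.0
  retirement_age: 65.0
employment:
  depression_unemployed: 0.54
  depression_parttime: 0.13
  remission_unemployed: 0.23
unit_costs:
  ect_session: 558.0
  esketamine_per_28mg: 163.0
  travel_per_visit: 18.800000000000001
  gp_visit: 39.0
  psychiatrist_visit: 170.0
  nurse_visit: 12.0
cost_table:
- entry: ect_acute
  class: depression
  total_lt65: 7932.0
  total_ge65: 6321.0
  direct: 6170.600000000000364
  n_visits: 8.0
- entry: esk_acute
  class: depression
  total_lt65: 7210.0
  total_ge65: 5599.0
  direct: 5004.800000000000182
  n_visits: 8.0
- entry: b_standard
  class: remission
  total_lt65: 701.0
  total_ge65: 118.0
  direct: 49.0
  n_visits: 0.0
- entry: mect_month1
  class: remission
  total_lt65: 3313.0
  total_ge65: 2730.0
  direct: 2654.800000000000182
  n_visits: 4.0
- entry: mect_ongoing
  class: remission
  total_lt65: 2161.0
  total_ge65: 1578.0
  direct: 1540.400000000000091
  n_visits: 2.0
- entry: esk_month1
  class: remission
  total_lt65: 2882.0
  total_ge65: 2299.0
  direct: 2223.800000000000182
  n_visits: 4.0
- entry: esk_month2to5
  class: remission
  total_lt65: 1583.0
  total_ge65: 1000.0
  direct: 962.399999999999977
  n_visits: 2.0
- entry: esk_month6
  class: remission
  total_lt65: 1890.0
  total_ge65: 1307.0
  direct: 1288.200000000000045
  n_visits: 1.0
- entry: state_d
  class: depression
  total_lt65: 2729.0
  total_ge65: 1119.0
  direct: 580.399999999999977
  n_visits: 0.0
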