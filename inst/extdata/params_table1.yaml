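incidence_by_age:
  40-44: 0.00061
  45-49: 0.0010056
  50-54: 0.001165
  55-59: 0.0011179
  60-64: 0.0010458
  65-69: 0.0009782
  70-74: 0.0009912
  75-79: 0.0009067
  80-84: 0.0007803
  85+: 0.000643
dcis_ratio: 0.12
rr_dcis_to_invasive: 2.02
rr_high_risk: 2.0
progression:
  I_II: 0.06
  II_III: 0.11
  III_IV: 0.15
  IV_death: 0.23
symptom_prob:
  I: 0.004
  II: 0.014
  III: 0.38
  IV: 0.98
fatality_treated:
  I: 0.006
  II: 0.042
  III: 0.093
  IV: 0.275
test_perf:
  us_then_mammo:
    sensitivity:
      baseline: 0.848
      min: 0.681
      max: 0.949
    specificity:
      baseline: 0.994
      min: 0.99
      max: 0.996
  us_plus_mammo:
    sensitivity:
      baseline: 0.939
      min: 0.798
      max: 0.993
    specificity:
      baseline: 0.98
      min: 0.975
      max: 0.985
utility:
  I:
    baseline: 0.79
    min: 0.77
    max: 0.8
  II:
    baseline: 0.79
    min: 0.78
    max: 0.8
  III:
    baseline: 0.77
    min: 0.76
    max: 0.79
  IV:
    baseline: 0.69
    min: 0.65
    max: 0.72
disutility_fp:
  baseline: 0.25
  min: 0.11
  max: 0.34
fp_duration_years: 0.095822154082
costs:
  questionnaire:
    baseline: 1.6
    min: 1.1
    max: 2.1
  screening:
    baseline: 85.5
    min: 59.8
    max: 111.1
  biopsy:
    baseline: 45.6
    min: 31.0
    max: 59.3
  treatment:
    DCIS:
      baseline: 2435.0
      min: 1705.0
      max: 3166.0
    I:
      baseline: 10067.0
      min: 7047.0
      max: 13087.0
    II:
      baseline: 11068.0
      min: 7748.0
      max: 14388.0
    III:
      baseline: 12867.0
      min: 9007.0
      max: 16727.0
    IV:
      baseline: 17766.0
      min: 12436.0
      max: 23096.0
discount_rate: 0.03
wtp_threshold: 23050.0
high_risk_comparator: yes
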