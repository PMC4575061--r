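meta:
  currency: CAD
  price_year: 2014.0
  note: 'Costs are per patient screened/serviced, CAD, pre-converted to the price
    year (literature Euro amounts converted and inflation-adjusted upstream). No death
    state: all-cause mortality is deliberately absent, a recognised limitation.'
  calibration: Transition probabilities, prevalence, state costs and programme costs
    back-solved from the published summary tables; see the methods vignette.
settings:
  horizon: 30
  discount_rate: 0.03
  wtp: 40000.0
  timing: half
  entry_state: at_risk
  psa:
    n_samples: 1000
    seed: 42
parameters:
  prevalence:
    value: 0.40511182737184198
    dist: beta
    se: 0.04
    source: calibrated
  sensitivity:
    value: 0.86499999999999999
    dist: beta
    se: 0.02
    source: paper
  specificity:
    value: 0.78600000000000003
    dist: beta
    se: 0.02
    source: paper
  utility_at_risk:
    value: 1.0
    dist: fixed
    se: 0.0
    source: assumption
  utility_mild:
    value: 0.87
    dist: beta
    se: 0.02
    source: paper
  utility_moderate:
    value: 0.79000000000000004
    dist: beta
    se: 0.02
    source: paper
  utility_severe:
    value: 0.64000000000000001
    dist: beta
    se: 0.02
    source: paper
  utility_blind:
    value: 0.5
    dist: beta
    se: 0.02
    source: paper
  cost_at_risk:
    value: 20.0
    dist: gamma
    se: 6.0
    source: calibrated
  cost_mild:
    value: 31.71202339094530132
    dist: gamma
    se: 10.0
    source: calibrated
  cost_moderate:
    value: 49.32981416369270278
    dist: gamma
    se: 15.0
    source: calibrated
  cost_severe:
    value: 70.47116309098950637
    dist: gamma
    se: 22.0
    source: calibrated
  cost_blind:
    value: 140.94232618197901274
    dist: gamma
    se: 45.0
    source: calibrated
  cost_screen_tele:
    value: 133.01558715529100141
    dist: gamma
    se: 30.0
    source: calibrated
  cost_service_inperson:
    value: 3643.8740196436901897
    dist: gamma
    se: 1070.0
    source: calibrated
  cost_confirmatory:
    value: 150.0
    dist: gamma
    se: 38.0
    source: calibrated
  tp_treated_at_risk_mild:
    value: 0.28827460248593301
    dist: beta
    se: 0.029
    source: calibrated
  tp_treated_mild_moderate:
    value: 0.0693438741247948
    dist: beta
    se: 0.007
    source: calibrated
  tp_treated_moderate_severe:
    value: 0.16553925824000301
    dist: beta
    se: 0.017
    source: calibrated
  tp_treated_severe_blind:
    value: 0.237676745967632
    dist: beta
    se: 0.024
    source: calibrated
  tp_untreated_at_risk_mild:
    value: 0.12300744039490499
    dist: beta
    se: 0.012
    source: calibrated
  tp_untreated_mild_moderate:
    value: 0.16402642620178301
    dist: beta
    se: 0.016
    source: calibrated
  tp_untreated_moderate_severe:
    value: 0.32789831842679101
    dist: beta
    se: 0.033
    source: calibrated
  tp_untreated_severe_blind:
    value: 0.49189035304261303
    dist: beta
    se: 0.049
    source: calibrated
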