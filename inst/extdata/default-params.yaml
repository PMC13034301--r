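prior:
  intercept: 63.399999999999999
  sd: 10.0
  effects:
    categorical:
      chronic_hypertension: -9.0
      sle_aps: -6.0
      smoker: 0.5
      family_history_pe: -2.0
      ethnic_group:black: -3.0
      ethnic_group:south_asian: -1.5
      ethnic_group:east_asian: -0.5
      ethnic_group:mixed: -1.0
      parity:nulliparous: -1.5
      parity:parous_prior_pe: -7.0
      diabetes:type1: -6.0
      diabetes:type2: -4.0
      conception:assisted: -2.0
    linear:
      weight:
        coef: -0.07
        center: 69.0
      height:
        coef: 0.05
        center: 164.0
      age:
        coef: -0.12
        center: 31.0
      interpregnancy_interval:
        coef: -0.2
        center: 2.9
markers:
  MAP:
    regression:
      intercept: 1.929418925714293
      categorical:
        chronic_hypertension: 0.045
        ethnic_group:black: 0.005
        smoker: -0.004
      linear:
        weight:
          coef: 0.0013
          center: 69.0
        age:
          coef: 0.0006
          center: 31.0
    slope: -0.005
    changepoint: 42.0
  UTAPI:
    regression:
      intercept: 0.204119982655925
      categorical:
        ethnic_group:black: 0.02
      linear:
        weight:
          coef: -0.0012
          center: 69.0
        ga_screening:
          coef: -0.03
          center: 12.699999999999999
    slope: -0.018
    changepoint: 42.0
  PLGF:
    regression:
      intercept: 1.602059991327963
      categorical:
        ethnic_group:black: 0.08
        smoker: 0.1
      linear:
        weight:
          coef: -0.003
          center: 69.0
        ga_screening:
          coef: 0.09
          center: 12.699999999999999
    slope: 0.025
    changepoint: 42.0
sigma:
- - 0.001444
  - 0.000228
  - -0.000323
- - 0.000228
  - 0.0144
  - -0.00306
- - -0.000323
  - -0.00306
  - 0.0289
grid:
  min: 24.0
  max: 42.0
  step: 0.05
band_cuts:
- 32.0
- 34.0
- 37.0
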