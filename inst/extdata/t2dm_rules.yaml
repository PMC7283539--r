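# Rule-based T2DM algorithm configuration: case decision paths over the
# evidence atoms (t1dm_dx, t2dm_dx, t1dm_med, t2dm_med, abnormal_lab) plus
# medication-precedence and physician-diagnosis-count requirements, and the
# laboratory abnormality thresholds. Absent atoms are "don't care".
paths:
  - id: P1
    require: {t1dm_dx: false, t2dm_dx: true, t2dm_med: true}
  - id: P2
    require: {t1dm_dx: false, t2dm_dx: true, t2dm_med: false, abnormal_lab: true}
  - id: P3
    require: {t1dm_dx: false, t2dm_dx: false, t2dm_med: true, abnormal_lab: true}
  - id: P4
    require: {t1dm_dx: true, t2dm_dx: true, t1dm_med: true, t2dm_med: true}
    require_precedence: true
  - id: P5
    require: {t1dm_dx: true, t2dm_dx: true, t1dm_med: true, t2dm_med: false}
    min_physician_dx: 2
lab_criteria:
  fasting_glucose_threshold: 126
  random_glucose_threshold: 200
  hba1c_threshold: 6.5
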