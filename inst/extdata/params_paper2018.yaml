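severity_transitions:
  50-59:
    normal:
    - 0.957507097673942
    - 0.041121778175966
    - 0.001370725939199
    - 1.991054466427529e-07
    - 1.991054466427529e-07
    mild:
    - 0.0
    - 0.93068356758702
    - 0.069276446008357
    - 1.999320231121419e-05
    - 1.999320231121419e-05
    moderate:
    - 0.0
    - 0.0
    - 0.999139879583142
    - 0.000430060208429
    - 0.000430060208429
    severe:
    - 0.0
    - 0.0
    - 0.0
    - 0.999570184820527
    - 0.000429815179473
    profound:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 1.0
  60-69:
    normal:
    - 0.96724900858477
    - 0.032408343203874
    - 0.000330084977076
    - 6.281617139516398e-06
    - 6.281617139516398e-06
    mild:
    - 0.0
    - 0.979058743524612
    - 0.019801188071284
    - 0.000570034202052
    - 0.000570034202052
    moderate:
    - 0.0
    - 0.0
    - 0.890356142456983
    - 0.054821928771509
    - 0.054821928771509
    severe:
    - 0.0
    - 0.0
    - 0.0
    - 0.945189037807562
    - 0.054810962192438
    profound:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 1.0
  70+:
    normal:
    - 0.963934163296647
    - 0.035497575515592
    - 0.000559961754612
    - 4.149716574357972e-06
    - 4.149716574357972e-06
    mild:
    - 0.0
    - 0.970232855885413
    - 0.029106985676562
    - 0.000330079219013
    - 0.000330079219013
    moderate:
    - 0.0
    - 0.0
    - 0.956
    - 0.022
    - 0.022
    severe:
    - 0.0
    - 0.0
    - 0.0
    - 0.978
    - 0.022
    profound:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 1.0
pathway:
  p_functional_impairment:
    normal: 0.18
    mild: 0.22
    moderate: 0.26
    severe: 0.26
    profound: 0.26
  p_receive_ha:
    mild: 0.3
    moderate: 0.52
    severe: 0.71
    profound: 0.71
    profound_ci: 0.58
  p_need_ci: 0.6
  p_ha_nonuse:
    mild: 0.13
    moderate: 0.3
    severe: 0.3
    profound: 0.3
    profound_ci: 0.03
  p_ci_failure: 0.03
  p_major_complication_y1: 0.04
utilities:
  base:
    normal: 0.95
    mild: 0.8
    moderate: 0.73
    severe: 0.73
    profound: 0.46
  functional:
    normal: 0.79
    mild: 0.74
    moderate: 0.67
    severe: 0.67
    profound: 0.26
  aided:
    mild: 0.89
    moderate: 0.9
    severe: 0.9
    profound: 0.64
  aided_functional:
    mild: 0.83
    moderate: 0.84
    severe: 0.84
    profound: 0.43
  ci: 0.61
  se_base:
    normal: 0.08
    mild: 0.03
    moderate: 0.03
    severe: 0.03
    profound: 0.21
  se_ci: 0.19
costs:
  ha_monaural: 275.0
  ha_binaural: 380.0
  p_binaural: 0.58
  ha_aftercare: 26.0
  hearing_evaluation: 54.0
  p_assess_no_ha:
    mild: 0.3
    moderate_plus: 0.05
  ci_device: 22919.0
  ci_candidacy: 5308.0
  p_assess_no_ci: 0.4
  ci_maintenance_y1: 6617.0
  ci_maintenance: 945.0
  ci_upgrade: 5445.0
  ci_upgrade_interval: 5.0
  major_complication: 10292.0
  therapy_price: 0.0
  ha_refit_interval: 5.0
  charge_evaluation_on_therapy: yes
settings:
  discount_rate: 0.035
  wtp: 20000.0
  cycle_length: 1.0
  entry_age: 50.0
  max_age: 110.0
  cohort_size: 1000.0
  init_severity:
    normal: 1.0
    mild: 0.0
    moderate: 0.0
    severe: 0.0
    profound: 0.0
  half_cycle_correction: no
  aftercare_for_nonusers: yes
  uptake_timing: annual
  ha_nonuse: transition
mortality:
  makeham: 0.0002
  slope: 0.002252
  rate: 0.1
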