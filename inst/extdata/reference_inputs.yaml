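schema: sccapacity-config-v1
# Reference per-cycle stage times, yearly regimen schedules and case mix
# for rituximab and trastuzumab across Spanish reference hospitals.
profiles:
  - {drug: rituximab, route: IV, phase: combo, waiting_min: 71, chair_min: 296, consultation_min: 20}
  - {drug: rituximab, route: SC, phase: combo, waiting_min: 71, chair_min: 139, consultation_min: 20}
  - {drug: rituximab, route: IV, phase: maintenance, waiting_min: 68, chair_min: 183, consultation_min: 16}
  - {drug: rituximab, route: SC, phase: maintenance, waiting_min: 53, chair_min: 21, consultation_min: 15}
  - {drug: trastuzumab, route: IV, phase: loading_combo, waiting_min: 83, chair_min: 187, consultation_min: 17}
  - {drug: trastuzumab, route: SC, phase: loading_combo, waiting_min: 83, chair_min: 83, consultation_min: 16}
  - {drug: trastuzumab, route: IV, phase: combo, waiting_min: 85, chair_min: 162, consultation_min: 17}
  - {drug: trastuzumab, route: SC, phase: combo, waiting_min: 85, chair_min: 107, consultation_min: 16}
  - {drug: trastuzumab, route: IV, phase: maintenance, waiting_min: 85, chair_min: 64, consultation_min: 17}
  - {drug: trastuzumab, route: SC, phase: maintenance, waiting_min: 60, chair_min: 15, consultation_min: 16}
schedules:
  - {drug: rituximab, indication_id: fl_first_line, n_loading_cycles: 0, n_combo_cycles: 8, n_maintenance_cycles: 12, first_cycle_always_iv: true}
  - {drug: rituximab, indication_id: fl_relapsed, n_loading_cycles: 0, n_combo_cycles: 8, n_maintenance_cycles: 8, first_cycle_always_iv: true}
  - {drug: rituximab, indication_id: dlbcl, n_loading_cycles: 0, n_combo_cycles: 8, n_maintenance_cycles: 0, first_cycle_always_iv: true}
  - {drug: trastuzumab, indication_id: breast_cancer, n_loading_cycles: 1, n_combo_cycles: 7, n_maintenance_cycles: 10, first_cycle_always_iv: false}
case_mix:
  - {drug: rituximab, indication_id: fl_first_line, share: 0.48}
  - {drug: rituximab, indication_id: fl_relapsed, share: 0.14}
  - {drug: rituximab, indication_id: dlbcl, share: 0.38}
  - {drug: trastuzumab, indication_id: breast_cancer, share: 1.0}
labor:
  annual_gross_salary_eur: 23022.20
  working_hours_per_month: 155.6
scenario:
  mode: both
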