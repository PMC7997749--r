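# Respiratory-department case-study instance: 28-day cycle, three elective
# patient types, bed / examination / nursing resources. Bed availability is
# the 70% elective share of 290 beds (30% reserved for emergencies). The
# admission cap is set non-binding (28 x 203); the priority floor to 0.
horizon: 28
admission_cap: 5684
priority_floor: 0.0
los_csv: base_los_survival.csv
patient_types:
- id: type_I
  revenue: 170.0
  exam_hours: 1.5
  nursing_hours: 1.5
  priority_score: 9.0
  mix_lower: 0.5
  mix_upper: 0.7
- id: type_II
  revenue: 160.0
  exam_hours: 1.0
  nursing_hours: 1.0
  priority_score: 6.5
  mix_lower: 0.1
  mix_upper: 0.2
- id: type_III
  revenue: 150.0
  exam_hours: 1.5
  nursing_hours: 0.5
  priority_score: 3.0
  mix_lower: 0.0
  mix_upper: 0.1
resources:
- id: bed
  available: 203.0
  target: 183.0
  cost_pos: 20.0
  cost_neg: 30.0
- id: exam
  available: 201.6
  target: 181.0
  cost_pos: 20.0
  cost_neg: 30.0
- id: nursing
  available: 561.0
  target: 512.0
  cost_pos: 20.0
  cost_neg: 30.0
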