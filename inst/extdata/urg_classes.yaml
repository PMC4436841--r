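- code: AA
  max_wait_days: 15.0
  urgency_coefficient: 24.0
- code: A
  max_wait_days: 30.0
  urgency_coefficient: 12.0
- code: B
  max_wait_days: 60.0
  urgency_coefficient: 6.0
- code: C
  max_wait_days: 180.0
  urgency_coefficient: 2.0
- code: D
  max_wait_days: 360.0
  urgency_coefficient: 1.0
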