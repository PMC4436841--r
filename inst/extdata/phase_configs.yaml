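- index: 1.0
  weeks_ahead: 5.0
  eligible_urgs:
  - B
  - C
  - D
  fill_urgs: []
  cumulative_utilization_cap: 0.5
- index: 2.0
  weeks_ahead: 3.0
  eligible_urgs: A
  fill_urgs:
  - B
  - C
  - D
  cumulative_utilization_cap: 0.75
- index: 3.0
  weeks_ahead: 1.0
  eligible_urgs: AA
  fill_urgs: []
  cumulative_utilization_cap: 1.0
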