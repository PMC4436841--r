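- name: Premature
  induction_pct: 25.0
  operating_pct: 0.0
  awakening_pct: 25.0
- name: Baby
  induction_pct: 25.0
  operating_pct: 0.0
  awakening_pct: 0.0
- name: HeartDisease
  induction_pct: 100.0
  operating_pct: 0.0
  awakening_pct: 50.0
- name: Coagulopathy
  induction_pct: 50.0
  operating_pct: 50.0
  awakening_pct: 0.0
- name: PsychoMotorPathology
  induction_pct: 50.0
  operating_pct: 0.0
  awakening_pct: 50.0
- name: Allergies
  induction_pct: 25.0
  operating_pct: 0.0
  awakening_pct: 25.0
- name: ParticularSyndromes
  induction_pct: 25.0
  operating_pct: 0.0
  awakening_pct: 25.0
- name: NeuromuscularPathology
  induction_pct: 25.0
  operating_pct: 0.0
  awakening_pct: 25.0
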