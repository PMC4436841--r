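- code: A
  intubation: no
  uses_prep_room: never
  induction_staff: 1
  operating_staff: 1
  recovery_staff: 1
  anesthesia_task_min: 10.0
  end_anesthesia_task_min: 10.0
  prep_room_task_min: ~
  prep_cleaning_min: 15.0
  table6_induction_min: 10.0
- code: B
  intubation: yes
  uses_prep_room: never
  induction_staff: 1
  operating_staff: 1
  recovery_staff: 1
  anesthesia_task_min: 15.0
  end_anesthesia_task_min: 15.0
  prep_room_task_min: ~
  prep_cleaning_min: 20.0
  table6_induction_min: 15.0
- code: C
  intubation: yes
  uses_prep_room: optional
  induction_staff: 2
  operating_staff: 1
  recovery_staff: 1
  anesthesia_task_min: 15.0
  end_anesthesia_task_min: 15.0
  prep_room_task_min: 30.0
  prep_cleaning_min: 40.0
  table6_induction_min: 30.0
- code: D
  intubation: yes
  uses_prep_room: optional
  induction_staff: 2
  operating_staff: 2
  recovery_staff: 1
  anesthesia_task_min: 15.0
  end_anesthesia_task_min: 15.0
  prep_room_task_min: 45.0
  prep_cleaning_min: 60.0
  table6_induction_min: 45.0
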