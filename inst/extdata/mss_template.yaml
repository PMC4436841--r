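duration_min: 360.0
start_times:
  morning: '08:00'
  afternoon: '14:00'
rooms:
  OR1:
    Mon:
      morning: Maxillo-Facial Plastic
      afternoon: Neurosurgery
    Tue:
      morning: Otolaryngology
      afternoon: Urology
    Wed:
      morning: Neurosurgery
      afternoon: Neurosurgery
    Thu:
      morning: Neurosurgery
      afternoon: Urology
    Fri:
      morning: Maxillo-Facial Plastic
      afternoon: Maxillo-Facial Plastic
  OR2:
    Mon:
      morning: General
      afternoon: General
    Tue:
      morning: Neonatal
      afternoon: Neonatal
    Wed:
      morning: Hepatobiliary
      afternoon: Hepatobiliary
    Thu:
      morning: Urology
      afternoon: Urology
    Fri:
      morning: Orthopedy
      afternoon: Urology
  OR3:
    Mon:
      morning: Urology
      afternoon: Urology
    Tue:
      morning: Gastrointestinal
      afternoon: Orthopedy
    Wed:
      morning: Orthopedy
      afternoon: Orthopedy
    Thu:
      morning: Neonatal
      afternoon: General
    Fri:
      morning: Urology
      afternoon: Urology
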