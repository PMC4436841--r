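transport_same_building_min: 10.0
transport_diff_building_min: 20.0
enter_sector_min: 10.0
enter_theatre_min: 10.0
exit_to_icu_min: 10.0
exit_to_recovery_min: 5.0
recovery_stay_min: 30.0
transport_icu_min: 10.0
transport_ward_same_min: 10.0
transport_ward_diff_min: 20.0
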