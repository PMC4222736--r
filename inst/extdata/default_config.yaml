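# Transform constants for the pressure chain and ejection-phase defaults.
# Units are stated in each key name.
aortic_systolic_offset_mmHg: 2.25       # brachial systolic -> aortic systolic
aortic_diastolic_offset_mmHg: -5.45     # brachial diastolic -> aortic diastolic
ventricular_offset_mmHg: 5              # aortic systolic -> ventricular systolic peak
aortic_pulse_fraction: 0.35             # aortic waveform amplitude as a fraction of (VSP - ADP)
ejection_time_intercept_s: 0.413        # linear systolic-ejection-period model: ET = a + b * HR
ejection_time_slope_s_per_bpm: -0.0017
ejection_time_clamp_s: [0.15, 0.40]
mmHg_to_Pa: 133.322
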