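subject_id,heart_rate_bpm,brachial_sys_mmHg,brachial_dia_mmHg,aortic_sys_mmHg,aortic_dia_mmHg,ventricular_sys_mmHg,doppler_co_ml_min,numerical_co_ml_min,ejection_time_s
subject01,98,,,147,68,152,11356,10916.97,
subject01,106,,,153,65,158,12651,12478.27,
subject01,114,,,160,63,165,14051,14031.32,
subject01,125,,,164,63,169,15298,15487.93,
subject01,136,,,169,64,174,16172,16686.83,
subject01,147,,,173,65,178,17225,18012.27,
subject01,153,,,175,66,180,17330,18445.6,
subject01,159,,,177,67,182,17941,18844.08,
subject01,169,,,181,68,186,18849,19817.15,
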