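status,age_group,n,n_male,n_female,smoking_duration_mean,followup_mean,cessation_mean
former,19-29,13,8,5,9.5,5.01,2.62
former,30-39,32,23,9,18.3,4.40,2.75
former,40-49,29,21,8,26.1,4.73,3.31
former,50-59,32,16,16,32.5,4.19,3.38
former,>=60,27,20,7,41.4,4.47,3.67
current,19-29,17,11,6,9.0,3.60,
current,30-39,26,18,8,17.9,4.00,
current,40-49,32,19,13,27.7,3.52,
current,50-59,36,23,13,37.2,3.78,
current,>=60,15,8,7,43.3,4.22,
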