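group,n,n_male,n_female,age_mean,age_sd,smoking_duration_mean,smoking_duration_sd,gmr_mean,gmr_sd,followup_mean,followup_sd,cessation_mean,cessation_sd
former,133,88,45,46.8,13.4,27.3,12.6,26.0,18.4,4.50,2.15,3.14,1.95
current,126,79,47,44.6,13.0,27.7,12.4,27.5,21.1,3.79,1.17,,
total,259,167,92,45.9,13.2,27.5,12.5,26.7,19.8,4.15,1.77,,
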