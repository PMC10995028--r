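variable,kind,n_esc,n_cbasp,mean_esc,sd_esc,mean_cbasp,sd_cbasp,count_esc,count_cbasp
female,nominal,28,22,,,,,17,8
age,metric,28,22,40.2,10.8,46.4,9.9,,
early_onset,nominal,28,22,,,,,12,17
suicide_attempts,metric,28,22,0.50,0.8,0.1,0.4,,
trauma,nominal,28,22,,,,,23,12
adverse_events,metric,28,22,2.1,1.2,1.4,0.8,,
prev_antidepressants_ge1,nominal,28,22,,,,,15,13
madrs_baseline,metric,28,22,28.4,8.1,24.4,8.8,,
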