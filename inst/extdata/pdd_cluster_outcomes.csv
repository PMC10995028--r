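cluster,n,madrs_baseline_mean,madrs_baseline_sd,madrs_week8_mean,madrs_week8_sd,pct_change_mean,pct_change_sd,response_rate,remission_rate
BeESC_TrESC,12,30.1,6.9,15.1,11.2,-50.9,35.4,58.3,33.3
BeCBASP_TrCBASP,10,26.8,8.5,17.5,6.9,-33.3,22.3,20.0,10.0
BeCBASP_TrESC,12,22.3,8.9,22.4,9.4,6.9,37.3,8.3,8.3
BeESC_TrCBASP,16,27.2,9.0,27.3,8.4,5.0,28.7,0.0,0.0
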