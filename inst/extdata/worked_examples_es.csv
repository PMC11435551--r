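parameter,pair,mean_asym,mean_without,sd_without,es_printed,printed_decimals
stance_ms,T-TA,583.8,706.9,11.5,-10.7,1
stance_ms,T-TA,714.1,719.5,11.7,-0.46,2
single_stance_ms,T-TA,314.9,395.3,16.2,-4.96,2
double_stance_ms,T-TA,297.9,310.6,16.0,-0.79,2
swing_ms,T-TA,420.7,408.3,10.4,1.19,2
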