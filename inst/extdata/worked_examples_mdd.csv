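parameter,group,sem,mdd95_printed,printed_decimals
mean_force,O,0.31,0.86,2
mean_force,O,0.34,0.94,2
mean_force,T,0.09,0.25,2
mean_force,T,0.14,0.39,2
mean_force,TA,0.08,0.22,2
mean_force,TA,0.31,0.86,2
stance_ms,O,42.89,118.89,2
stance_ms,O,47.82,132.55,2
stance_ms,T,3.44,9.54,2
stance_ms,T,6.14,17.02,2
stance_ms,TA,0.91,2.52,2
stance_ms,TA,12.17,33.73,2
single_stance_ms,O,23.99,66.5,1
single_stance_ms,O,29.22,80.99,2
single_stance_ms,T,3.17,8.79,2
single_stance_ms,T,6.3,17.46,2
single_stance_ms,TA,1.8,4.99,2
single_stance_ms,TA,8.84,24.5,1
double_stance_ms,O,19.28,53.44,2
double_stance_ms,O,19.76,54.77,2
double_stance_ms,T,2,5.54,2
double_stance_ms,T,2.37,6.57,2
double_stance_ms,TA,1.43,3.96,2
double_stance_ms,TA,5.12,14.19,2
swing_ms,O,24.24,67.19,2
swing_ms,O,29.04,80.49,2
swing_ms,T,2.45,6.79,2
swing_ms,T,6.77,18.77,2
swing_ms,TA,1.77,4.91,2
swing_ms,TA,8.32,23.06,2
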