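code,rho_f,lwr,model,gas_bearing,density_provenance,lw_a,lw_b,sl_p25,sl_mean,sl_median,sl_p75,n_sl
KRA,1038.39,12.42,PS,TRUE,measured,5.287e-06,3,35,45.09,43,58.5,964
PRM,1061.67,11.36,PS,TRUE,measured,6.4613e-06,3,37,43.94,45,51,619
PRE,1053.83,11.39,PS,TRUE,group_mean,6.3799e-06,3,33,39.33,42,47,145
ELC,1061.44,9.13,PS,TRUE,measured,1.0001e-05,3,73,75.64,76,78,251
ELN_S,1038,10.14,PS,TRUE,measured,7.9289e-06,3,42,44.75,46,49,335
ELN_L,1038,10.14,FC,FALSE,measured,7.9289e-06,3,64,74.48,74,84,2220
GYR,1028.94,11.91,FC,FALSE,measured,5.6971e-06,3,67,84.22,86,103,1493
GYF,1064.14,10.86,FC,FALSE,measured,7.0865e-06,3,59,65.46,66,76,118
GYN,1043.38,9.51,FC,FALSE,group_mean,9.0609e-06,3,116,122.68,137,149,100
BAX,1037.05,8.08,FC,FALSE,measured,1.2476e-05,3,76,96.19,94,114,1578
NOE,1043.38,10.53,FC,FALSE,group_mean,7.3905e-06,3,63.75,76.07,72,83,185
YTX,1043.38,10.53,FC,FALSE,group_mean,7.3905e-06,3,40,48.23,45,57,669
KRI,,,SDWBA,FALSE,measured,2e-06,3.2,40,44,45,50,
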