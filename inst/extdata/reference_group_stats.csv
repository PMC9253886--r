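comparison,m1,sd1,m2,sd2,d_reported,consistent,note
delta_amplitude_vCA1_SAL_run_vs_sleep,0.210,0.129,0.135,0.028,0.80,TRUE,peak-to-peak amplitude (mV)
delta_amplitude_vCA1_VCD_run_vs_sleep,0.345,0.219,0.126,0.032,1.40,TRUE,peak-to-peak amplitude (mV)
delta_amplitude_mPFC_SAL_run_vs_sleep,0.216,0.129,0.115,0.011,1.11,TRUE,peak-to-peak amplitude (mV)
delta_amplitude_mPFC_VCD_run_vs_sleep,0.324,0.209,0.105,0.019,1.47,TRUE,peak-to-peak amplitude (mV)
delta_frequency_vCA1_SAL_run_vs_sleep,2.71,0.28,3.10,0.13,1.78,TRUE,frequency (Hz)
delta_frequency_vCA1_VCD_run_vs_sleep,2.52,0.48,3.26,0.19,2.01,FALSE,recomputes 2.03 from printed M/SD
delta_frequency_mPFC_SAL_run_vs_sleep,2.56,0.38,3.02,0.22,1.51,FALSE,recomputes 1.48 from printed M/SD
delta_frequency_mPFC_VCD_run_vs_sleep,2.51,0.46,3.10,0.20,1.69,FALSE,recomputes 1.66 from printed M/SD
delta_sync_run_SAL_vs_VCD,0.891,0.125,0.883,0.160,0.05,TRUE,cross-correlation of delta-filtered segments
delta_sync_sleep_SAL_vs_VCD,0.589,0.147,0.365,0.133,1.60,TRUE,cross-correlation of delta-filtered segments
awake_pct_SAL_light_vs_dark,38.50,30.09,57.03,38.03,0.54,TRUE,percent of 12 h cycle
awake_pct_VCD_light_vs_dark,39.57,31.69,55.04,36.19,0.45,TRUE,percent of 12 h cycle
nrem_pct_SAL_light_vs_dark,48.33,24.34,25.00,32.00,0.82,TRUE,percent of 12 h cycle
nrem_pct_VCD_light_vs_dark,52.68,29.13,28.61,29.39,0.82,TRUE,percent of 12 h cycle
rem_pct_SAL_light_vs_dark,11.08,11.80,9.53,21.20,0.09,TRUE,percent of 12 h cycle
rem_pct_VCD_light_vs_dark,7.09,10.26,17.57,27.73,0.50,TRUE,percent of 12 h cycle
awake_pct_light_SAL_vs_VCD,38.50,30.09,39.57,31.69,0.03,TRUE,percent of 12 h cycle
nrem_pct_light_SAL_vs_VCD,48.33,24.34,52.68,29.13,0.16,TRUE,percent of 12 h cycle
rem_pct_light_SAL_vs_VCD,11.08,11.80,7.09,10.26,0.36,TRUE,percent of 12 h cycle
awake_pct_dark_SAL_vs_VCD,57.03,38.03,55.04,36.19,0.05,TRUE,percent of 12 h cycle
nrem_pct_dark_SAL_vs_VCD,25.00,32.00,28.61,29.39,0.12,TRUE,percent of 12 h cycle
rem_pct_dark_SAL_vs_VCD,9.53,21.20,17.57,27.73,0.33,TRUE,percent of 12 h cycle
spwr_spindle_ratio_SAL_vs_VCD,4.70,0.80,6.07,1.59,1.08,TRUE,ripple:spindle count ratio
fraction_followed_SAL_vs_VCD,14.40,2.11,12.26,2.40,0.94,TRUE,percent of ripples followed by a spindle
ripple_frequency_SAL_vs_VCD,176.6,20.21,177.2,22.41,0.028,TRUE,per-event ripple frequency (Hz)
spwr_spindle_latency_SAL_vs_VCD,2.16,2.98,1.79,2.40,0.13,TRUE,latency (s)
spwr_rate_SAL_vs_VCD,0.44,0.057,0.52,0.047,-0.94,FALSE,printed sign and magnitude inconsistent with ABS formula (recomputes 1.53)
spindle_rate_SAL_vs_VCD,0.095,0.0055,0.087,0.0060,0.70,FALSE,recomputes 1.39; likely SEM/SD mix-up in source
wheel_latency_SAL_vs_VCD,162.21,6.47,2.77,0.87,1.29,FALSE,recomputes 34.5; summary statistics inconsistent
wheel_first_run_duration_SAL_vs_VCD,22.4,8.3,5.3,2.6,1.19,FALSE,recomputes 2.78; summary statistics inconsistent
wheel_light_total_run_SAL_vs_VCD,845.9,297.1,1384.2,118.2,1.01,FALSE,recomputes 2.38; summary statistics inconsistent
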