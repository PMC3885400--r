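fluence_J_cm2,avg_peak_pressure_MPa,avg_impulse_Pa_s,rat_id,scattering_change,eeg_suppression,long_hypoxemia,heme_reduction
0.75,63,9,1,FALSE,FALSE,FALSE,FALSE
0.75,63,9,2,TRUE,TRUE,TRUE,TRUE
0.75,63,9,3,FALSE,FALSE,FALSE,FALSE
0.75,63,9,4,TRUE,TRUE,TRUE,TRUE
0.75,63,9,5,FALSE,FALSE,FALSE,FALSE
1.0,86,14,1,TRUE,TRUE,FALSE,FALSE
1.0,86,14,2,FALSE,FALSE,FALSE,FALSE
1.0,86,14,3,TRUE,TRUE,TRUE,TRUE
1.0,86,14,4,TRUE,TRUE,TRUE,FALSE
1.0,86,14,5,TRUE,TRUE,TRUE,TRUE
1.0,86,14,6,TRUE,TRUE,TRUE,TRUE
1.0,86,14,7,TRUE,TRUE,TRUE,FALSE
1.0,86,14,8,TRUE,TRUE,TRUE,TRUE
1.0,86,14,9,FALSE,FALSE,FALSE,FALSE
1.0,86,14,10,FALSE,FALSE,FALSE,FALSE
1.0,86,14,11,TRUE,TRUE,TRUE,TRUE
1.0,86,14,12,TRUE,TRUE,TRUE,TRUE
1.25,104,19,1,TRUE,TRUE,TRUE,TRUE
1.25,104,19,2,TRUE,TRUE,TRUE,TRUE
1.25,104,19,3,TRUE,TRUE,TRUE,TRUE
1.25,104,19,4,TRUE,TRUE,FALSE,TRUE
1.25,104,19,5,TRUE,TRUE,TRUE,TRUE
1.5,123,23,1,TRUE,TRUE,FALSE,FALSE
1.5,123,23,2,TRUE,TRUE,TRUE,TRUE
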