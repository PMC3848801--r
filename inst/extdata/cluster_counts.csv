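feature,is_cluster,malignant_count,malignant_percent,benign_count,benign_percent,or_printed,or_ci_low_printed,or_ci_high_printed,p_printed
abdomen,TRUE,41,68.3,36,31.0,4.7,2.4,9.3,<0.01
pain,TRUE,33,55.0,26,22.4,4.2,2.1,8.2,<0.01
eating,TRUE,27,45.0,14,12.0,5.9,2.8,12.6,<0.01
miscellaneous,TRUE,21,35.0,18,15.4,2.9,1.4,6.0,0.01
digestion,TRUE,18,30.0,10,8.5,4.5,1.9,10.5,0.01
back_pain,FALSE,17,28.3,10,8.6,4.1,1.8,9.8,<0.01
able_to_feel_abdominal_mass,FALSE,14,23.3,11,9.4,2.9,1.2,6.8,0.02
bladder,TRUE,14,23.3,20,17.1,1.4,0.7,3.1,0.42
leg_swelling,FALSE,6,10.0,11,9.4,1.1,0.4,3.0,1.0
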