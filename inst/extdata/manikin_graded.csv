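gravity_g,plate_angle_deg,plate_angle_sd,orientation_deg,orientation_sd,target_pct,measured_pct,measured_sd,n_trials
0.00,90.0,0.0,89.7,0.5,0.0,2.0,0.6,30
0.05,87.1,0.0,89.8,1.0,5.0,5.4,0.8,30
0.10,84.3,0.0,90.0,0.9,10.0,11.1,0.5,30
0.15,81.4,0.0,89.5,1.0,15.0,17.0,0.7,30
0.17,80.5,0.0,89.8,1.0,17.0,18.4,0.9,30
0.20,78.5,0.0,90.0,0.9,20.0,23.0,0.8,30
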