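gravity_g,plate_angle_deg,plate_angle_sd,orientation_deg,orientation_sd,target_pct,measured_pct,measured_sd,n_trials
0.00,90.0,0.0,90.0,0.0,0.0,2.0,0.1,3
0.03,88.3,0.0,89.3,0.6,3.0,2.1,0.4,3
0.04,87.7,0.0,89.0,1.7,4.0,3.0,0.6,3
0.07,86.0,0.0,87.7,0.6,7.0,6.5,0.3,3
0.09,84.8,0.1,91.3,1.5,9.0,9.4,0.5,3
0.11,83.7,0.0,88.7,1.2,11.0,12.0,0.2,3
0.13,82.5,0.0,90.3,1.2,13.0,13.8,0.7,3
0.14,82.0,0.1,90.3,1.2,14.0,15.4,1.1,3
0.20,78.5,0.0,91.0,1.0,20.0,24.0,0.9,3
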