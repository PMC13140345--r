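rope,mass_fraction,height_fraction,bilateral
ankle,0.075,0.039,TRUE
knee,0.247,0.285,TRUE
pelvis,0.150,0.53,FALSE
thorax,0.528,0.81,FALSE
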