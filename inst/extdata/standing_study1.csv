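participant,earth_mass_kg,lunar_mass_kg,loading_pct,error_pct
1,69.8,13.2,19.0,2.5
2,79.7,13.6,17.1,0.6
3,77.6,17.6,22.7,6.2
4,96.2,18.7,19.4,2.9
5,79.0,15.5,19.6,3.1
6,95.6,19.3,20.2,3.7
7,68.8,12.1,17.6,1.1
8,65.2,11.2,17.2,0.7
9,87.4,18.8,21.5,5.0
10,86.1,16.4,19.1,2.6
11,74.7,14.4,19.2,2.7
12,66.7,13.2,19.9,3.3
13,71.1,16.8,23.6,7.1
14,54.0,9.7,18.0,1.5
15,87.4,17.8,20.4,3.9
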