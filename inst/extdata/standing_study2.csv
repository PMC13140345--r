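participant,earth_mass_kg,loading_v1,loading_v2,loading_v3,error_v1,error_v2,error_v3
1,64.6,17.6,18.7,18.0,1.1,2.2,1.5
2,69.0,20.8,19.1,17.4,4.3,2.6,0.9
3,68.7,16.3,NA,NA,-0.2,NA,NA
4,74.1,19.3,26.0,18.7,2.8,9.5,2.2
5,73.9,19.1,NA,NA,2.6,NA,NA
6,65.2,22.8,17.6,16.6,6.3,1.1,0.1
7,72.0,14.4,20.9,20.3,-2.1,4.4,3.8
8,62.9,16.9,18.3,20.6,0.4,1.8,4.1
9,77.8,16.5,16.4,16.0,0.0,-0.1,-0.5
10,60.6,17.5,NA,NA,1.0,NA,NA
11,59.6,19.3,16.6,19.8,2.8,0.1,3.3
12,59.4,18.3,NA,NA,1.8,NA,NA
13,76.0,14.2,NA,NA,-2.3,NA,NA
14,92.9,20.3,16.3,13.2,3.8,-0.2,-3.3
15,77.1,11.8,24.6,20.4,-4.7,8.1,3.9
16,66.5,14.5,20.5,15.6,-2.0,4.0,-0.9
17,87.5,15.6,16.4,14.8,-0.9,-0.1,-1.7
18,100.0,19.9,17.2,18.0,3.4,0.7,1.5
19,74.4,14.3,19.1,17.5,-2.2,2.6,1.0
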