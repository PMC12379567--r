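age_y,bw_kg,bone_g,brain_g,liver_g,kidney_g,rest_g,plasma_L
0,3.5,320,420,135,27,2100,0.14
0.25,6,500,640,210,42,3800,0.24
0.5,7.8,640,780,260,52,5000,0.31
1,10,850,1000,320,72,6700,0.4
2,12.5,1150,1150,420,95,8700,0.5
5,19,1900,1350,640,125,13400,0.76
10,32,3300,1400,950,185,24000,1.3
12,40,4100,1400,1100,210,30500,1.6
15,56,6000,1400,1500,270,44000,2.3
20,73,7500,1400,1800,310,57500,2.9
50,73,7500,1400,1800,310,57500,2.9
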