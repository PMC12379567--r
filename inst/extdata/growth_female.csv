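age_y,bw_kg,bone_g,brain_g,liver_g,kidney_g,rest_g,plasma_L
0,3.3,300,400,130,25,2000,0.13
0.25,5.6,480,620,200,40,3600,0.22
0.5,7.2,600,750,250,50,4700,0.29
1,9.5,800,950,300,70,6400,0.38
2,12,1100,1100,400,90,8300,0.48
5,18,1800,1250,600,120,12700,0.72
10,32,3200,1300,900,180,24000,1.3
12,40,4000,1300,1050,200,30500,1.6
15,54,5400,1300,1300,250,42500,2.2
20,60,6000,1300,1400,275,47500,2.4
50,60,6000,1300,1400,275,47500,2.4
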