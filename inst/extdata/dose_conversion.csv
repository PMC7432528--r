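energy_mev,h10_psv_cm2,note
0.010,0.061,ambient dose equivalent H*(10) per fluence
0.015,0.83,ambient dose equivalent H*(10) per fluence
0.020,1.05,ambient dose equivalent H*(10) per fluence
0.030,0.81,ambient dose equivalent H*(10) per fluence
0.040,0.64,ambient dose equivalent H*(10) per fluence
0.050,0.55,ambient dose equivalent H*(10) per fluence
0.060,0.51,ambient dose equivalent H*(10) per fluence
0.080,0.53,ambient dose equivalent H*(10) per fluence
0.100,0.61,ambient dose equivalent H*(10) per fluence
0.150,0.89,ambient dose equivalent H*(10) per fluence
0.200,1.20,ambient dose equivalent H*(10) per fluence
0.300,1.80,ambient dose equivalent H*(10) per fluence
0.400,2.38,ambient dose equivalent H*(10) per fluence
0.500,2.93,ambient dose equivalent H*(10) per fluence
0.600,3.44,ambient dose equivalent H*(10) per fluence
0.800,4.38,ambient dose equivalent H*(10) per fluence
1.000,5.20,ambient dose equivalent H*(10) per fluence
1.500,6.90,ambient dose equivalent H*(10) per fluence
2.000,8.60,ambient dose equivalent H*(10) per fluence
3.000,11.10,ambient dose equivalent H*(10) per fluence
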