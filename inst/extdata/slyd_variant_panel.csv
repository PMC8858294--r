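variant,kd_if_um,kd_if_se,dh_if_kcal,dh_if_se,kd_fkbp_um,kd_fkbp_se,dh_fkbp_kcal,dh_fkbp_se,act_wt,act_wt_se,kd_dif_um,kd_dif_se,dh_dif_kcal,dh_dif_se,act_dif,act_dif_se
psWT,0.22,0.01,-15.4,0.1,3.5,0.1,-6.4,0.2,4.9,0.3,15.6,0.2,-12,0.1,2.2,0.3
R2A,,,,,,,,,5.1,0.3,,,,,1.3,0.2
Y3A,0.72,0.1,-13.1,0.1,17.3,1.3,-11.3,0.5,3.9,0.4,51.5,8.6,-9.3,1.9,2.5,0.3
W4A,0.75,0.06,-15.6,0.1,8.4,0.4,-6.6,0.7,2.0,0.2,30.8,4.0,-6.6,0.7,1.1,0.2
W4E,0.86,0.02,-15.2,0.1,13.9,0.9,-5.1,0.7,4.4,0.2,19.6,3.4,-3.8,0.5,0.9,0.2
W4K,0.21,0.01,-15.5,0.1,3.2,0.3,-3.1,0.4,2.2,0.3,12.6,0.8,-4.4,0.2,3.5,0.7
M8A,0.24,0.01,-18.5,0.1,6.0,0.1,-9.3,0.2,7.7,0.9,19.4,1.0,-10,0.3,3.1,0.1
F13A,0.38,0.02,-17.6,0.1,6.4,0.3,-6.4,0.4,3.1,0.1,22.7,0.6,-15,0.3,0.4,0.1
F13E,1.15,0.01,-20.8,0.2,10.4,0.5,-5.0,0.8,7.0,0.6,36.1,0.8,-13,0.2,0.1,0.1
F13K,0.11,0.02,-18.1,0.1,5.2,0.2,-5.2,0.2,3.4,0.1,20.0,0.7,-10,0.3,2.3,0.3
G14M,0.10,0.01,-16.6,0.2,2.2,0.1,-8.2,0.3,,,8.3,0.5,-11,0.2,,
A15L,0.16,0.02,-14.3,0.2,4.1,0.1,-6.5,0.4,,,14.8,0.2,-10,0.1,,
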