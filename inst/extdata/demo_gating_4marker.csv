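Sample,Q1 | Freq. of Parent,Q2 | Freq. of Parent,Q3 | Freq. of Parent,Q4 | Freq. of Parent,Q1/Q1 | Freq. of Parent,Q1/Q2 | Freq. of Parent,Q1/Q3 | Freq. of Parent,Q1/Q4 | Freq. of Parent,Q2/Q1 | Freq. of Parent,Q2/Q2 | Freq. of Parent,Q2/Q3 | Freq. of Parent,Q2/Q4 | Freq. of Parent,Q3/Q1 | Freq. of Parent,Q3/Q2 | Freq. of Parent,Q3/Q3 | Freq. of Parent,Q3/Q4 | Freq. of Parent,Q4/Q1 | Freq. of Parent,Q4/Q2 | Freq. of Parent,Q4/Q3 | Freq. of Parent,Q4/Q4 | Freq. of Parent
A_01,24.800000,40.110000,10.620000,24.470000,13.346774,1.935484,47.096774,37.620968,6.831214,90.326602,2.842184,0.000000,41.713748,37.288136,8.380414,12.617702,4.413568,7.233347,0.040866,88.312219
A_02,25.770000,42.860000,10.930000,20.440000,9.778813,6.092355,44.470314,39.658518,9.286048,87.774148,2.939804,0.000000,30.375114,35.864593,14.455627,19.304666,3.424658,8.512720,0.195695,87.866928
A_03,23.180000,46.090000,9.000000,21.730000,6.945643,5.435720,56.125971,31.492666,4.794966,93.187242,2.017791,0.000000,38.888889,31.333333,11.555556,18.222222,10.584445,8.651634,0.276116,80.487805
B_01,34.630000,8.960000,13.510000,42.900000,20.877852,2.598903,58.215420,18.307826,17.410714,77.901786,3.013393,1.674107,81.421170,17.764619,0.740192,0.074019,23.356643,6.433566,0.769231,69.440559
B_02,40.280000,8.800000,10.780000,40.140000,17.701092,4.195631,60.402185,17.701092,14.090909,82.272727,0.000000,3.636364,81.261596,16.790353,1.762523,0.185529,22.247135,10.164425,1.420030,66.168411
B_03,38.260000,8.140000,12.900000,40.700000,20.700470,0.627287,62.780972,15.891270,14.496314,82.800983,2.088452,0.614251,70.155039,28.217054,0.232558,1.395349,22.457002,10.466830,1.916462,65.159705
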