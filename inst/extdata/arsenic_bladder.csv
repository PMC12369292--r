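study_id,location,water_intake,group_label,dose_low,dose_high,dose_median,midpoint,midpoint_printed,or,or_low,or_high,cases,noncases,n,eff_cases,eff_noncases,n_eff
Ferreccio2000,Chile,1.80,0-59,0,59,NA,NA,26.55,1,NA,NA,23,138,161,19,142,161
Ferreccio2000,Chile,1.80,60-199,60,199,NA,NA,116.55,0.84,0.46,1.52,27,193,220,22,198,220
Ferreccio2000,Chile,1.80,200-799,200,799,NA,NA,449.55,2.50,1.48,4.22,60,144,204,51,153,204
Ferreccio2000,Chile,1.80,>=800,800,NA,NA,NA,1080,4.44,2.75,7.15,122,165,287,107,180,287
Kurttio,Finland,1.60,<0.1,NA,0.1,NA,NA,0.04,1,NA,NA,26,112,138,13,125,138
Kurttio,Finland,1.60,0.1-0.5,0.1,0.5,NA,NA,0.24,0.81,0.41,1.63,18,51,69,5,64,69
Kurttio,Finland,1.60,>0.5,0.5,NA,NA,NA,0.6,1.51,0.67,3.38,17,51,68,9,59,68
Pu,Taiwan,2.23,<=27.8,NA,27.8,NA,NA,31.0,1,NA,NA,24,104,128,18,110,128
Pu,Taiwan,2.23,27.8-61.0,27.8,61.0,NA,NA,49.51,1.90,1.10,3.40,44,104,148,35,113,148
Pu,Taiwan,2.23,>61.0,61.0,NA,NA,NA,102.02,5.30,3.10,9.00,109,105,214,99,115,214
Steinmaus,Chile,1.80,<26,NA,26,NA,NA,11.7,1,NA,NA,33,202,235,14,221,235
Steinmaus,Chile,1.80,26-79,26,79,NA,NA,47.25,0.92,0.52,1.61,33,189,222,12,210,222
Steinmaus,Chile,1.80,80-197,80,197,NA,NA,124.65,2.62,1.53,4.50,71,142,213,30,183,213
Steinmaus,Chile,1.80,>197,197,NA,NA,NA,265.95,6.00,3.38,10.64,95,107,202,56,146,202
Wu,Taiwan,2.23,<15.5,NA,15.5,NA,NA,8.64,1,NA,NA,44,196,240,27,213,240
Wu,Taiwan,2.23,15.5-42.5,15.5,42.5,NA,NA,32.34,1.42,0.90,2.25,63,196,259,40,219,259
Wu,Taiwan,2.23,>42.5,42.5,NA,NA,NA,71.08,4.13,2.69,6.35,192,202,394,135,259,394
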