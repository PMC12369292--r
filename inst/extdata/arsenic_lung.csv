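study_id,location,water_intake,group_label,dose_low,dose_high,dose_median,midpoint,midpoint_printed,or,or_low,or_high,cases,noncases,n,eff_cases,eff_noncases,n_eff
Ferreccio1998,Chile,1.80,0-10,0,10,NA,NA,4.5,1,NA,NA,6,70,76,5,71,76
Ferreccio1998,Chile,1.80,10-29,10,29,NA,NA,17.55,1.70,0.50,5.10,9,68,77,8,69,77
Ferreccio1998,Chile,1.80,30-49,30,49,NA,NA,35.55,3.90,1.20,13.40,7,24,31,7,24,31
Ferreccio1998,Chile,1.80,50-199,50,199,NA,NA,112.05,5.50,2.20,13.50,52,130,182,51,131,182
Ferreccio1998,Chile,1.80,200-400,200,400,NA,NA,270,9.00,3.60,22.00,77,127,204,79,125,204
Ferreccio2000,Chile,1.80,0-59,0,59,NA,NA,26.55,1,NA,NA,48,138,186,32,154,186
Ferreccio2000,Chile,1.80,60-199,60,199,NA,NA,116.55,0.77,0.49,1.21,52,193,245,34,211,245
Ferreccio2000,Chile,1.80,200-799,200,799,NA,NA,449.55,1.38,0.89,2.13,69,144,213,48,165,213
Ferreccio2000,Chile,1.80,>=800,800,NA,NA,NA,1080,2.39,1.61,3.54,137,165,302,100,202,302
Mostafa,Bangladesh,3.50,0-10,0,10,NA,NA,8.75,1,NA,NA,354,186,540,109,431,540
Mostafa,Bangladesh,3.50,11-50,11,50,NA,NA,52.5,1.13,0.91,1.40,1303,576,1879,128,448,576
Mostafa,Bangladesh,3.50,51-100,51,100,NA,NA,131.25,1.28,0.92,1.77,208,84,292,71,221,292
Smith,USA,1.80,0-9,0,9,NA,NA,4.05,1,NA,NA,11,92,103,8,95,103
Smith,USA,1.80,10-59,10,59,NA,NA,31.05,0.70,0.30,1.70,7,81,88,5,83,88
Smith,USA,1.80,60-199,60,199,NA,NA,116.55,3.40,1.80,6.50,35,87,122,27,95,122
Smith,USA,1.80,200-399,200,399,NA,NA,269.55,4.70,2.00,11.00,23,44,67,19,48,67
Smith,USA,1.80,400-699,400,699,NA,NA,494.55,5.70,1.90,16.90,11,12,23,7,16,23
Smith,USA,1.80,700-999,700,999,NA,NA,764.55,7.10,3.40,14.80,64,103,167,62,105,167
Steinmaus,Chile,1.80,<26,NA,26,NA,NA,11.7,1,NA,NA,61,202,263,21,242,263
Steinmaus,Chile,1.80,26-79,26,79,NA,NA,47.25,0.98,0.62,1.53,61,189,250,20,230,250
Steinmaus,Chile,1.80,80-197,80,197,NA,NA,124.65,1.70,1.05,2.75,85,142,227,29,198,227
Steinmaus,Chile,1.80,>197,197,NA,NA,NA,265.95,3.18,1.90,5.30,99,107,206,45,161,206
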