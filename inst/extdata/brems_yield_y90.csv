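energy_keV,yield_per_keV
10,0.0259831
20,0.0128594
30,0.00848486
40,0.00629767
50,0.00498542
60,0.00411064
70,0.00348586
80,0.00301732
90,0.00265296
100,0.00236151
110,0.00212311
120,0.00192448
130,0.00175646
140,0.00161248
150,0.00148775
160,0.00137865
170,0.00128242
180,0.00119693
190,0.00112048
200,0.00105172
210,0.000989537
220,0.00093305
230,0.000881513
240,0.000834308
250,0.000790917
260,0.000750901
270,0.000713885
280,0.000679549
290,0.000647617
300,0.000617849
310,0.000590036
320,0.000563996
330,0.000539569
340,0.000516613
350,0.000495002
360,0.000474625
370,0.000455383
380,0.000437186
390,0.000419955
400,0.000403619
410,0.000388111
420,0.000373373
430,0.000359353
440,0.000346001
450,0.000333273
460,0.00032113
470,0.000309535
480,0.000298452
490,0.000287853
500,0.000277707
510,0.000267989
520,0.000258674
530,0.00024974
540,0.000241166
550,0.000232932
560,0.000225021
570,0.000217416
580,0.000210102
590,0.000203064
600,0.000196287
610,0.000189761
620,0.000183472
630,0.000177411
640,0.000171565
650,0.000165926
660,0.000160485
670,0.000155232
680,0.00015016
690,0.00014526
700,0.000140526
710,0.000135952
720,0.000131529
730,0.000127252
740,0.000123116
750,0.000119115
760,0.000115243
770,0.000111497
780,0.00010787
790,0.000104359
800,0.000100959
810,9.76659e-05
820,9.44767e-05
830,9.13872e-05
840,8.8394e-05
850,8.54937e-05
860,8.26831e-05
870,7.99591e-05
880,7.73189e-05
890,7.47597e-05
900,7.22787e-05
910,6.98735e-05
920,6.75416e-05
930,6.52806e-05
940,6.30882e-05
950,6.09624e-05
960,5.8901e-05
970,5.6902e-05
980,5.49636e-05
990,5.30838e-05
1000,5.12609e-05
1010,4.94931e-05
1020,4.77789e-05
1030,4.61166e-05
1040,4.45047e-05
1050,4.29417e-05
1060,4.14262e-05
1070,3.99569e-05
1080,3.85323e-05
1090,3.71512e-05
1100,3.58124e-05
1110,3.45147e-05
1120,3.32568e-05
1130,3.20377e-05
1140,3.08564e-05
1150,2.97116e-05
1160,2.86025e-05
1170,2.7528e-05
1180,2.64871e-05
1190,2.5479e-05
1200,2.45027e-05
1210,2.35574e-05
1220,2.26422e-05
1230,2.17563e-05
1240,2.08989e-05
1250,2.00691e-05
1260,1.92663e-05
1270,1.84898e-05
1280,1.77387e-05
1290,1.70124e-05
1300,1.63102e-05
1310,1.56315e-05
1320,1.49756e-05
1330,1.43419e-05
1340,1.37298e-05
1350,1.31387e-05
1360,1.25681e-05
1370,1.20172e-05
1380,1.14857e-05
1390,1.09729e-05
1400,1.04784e-05
1410,1.00016e-05
1420,9.54209e-06
1430,9.09932e-06
1440,8.67283e-06
1450,8.26216e-06
1460,7.86686e-06
1470,7.4865e-06
1480,7.12063e-06
1490,6.76886e-06
1500,6.43075e-06
1510,6.10592e-06
1520,5.79397e-06
1530,5.49452e-06
1540,5.20719e-06
1550,4.93163e-06
1560,4.66747e-06
1570,4.41437e-06
1580,4.17198e-06
1590,3.93997e-06
1600,3.71802e-06
1610,3.50581e-06
1620,3.30303e-06
1630,3.10937e-06
1640,2.92453e-06
1650,2.74823e-06
1660,2.58018e-06
1670,2.42011e-06
1680,2.26773e-06
1690,2.12279e-06
1700,1.98503e-06
1710,1.85419e-06
1720,1.73003e-06
1730,1.6123e-06
1740,1.50077e-06
1750,1.3952e-06
1760,1.29537e-06
1770,1.20107e-06
1780,1.11207e-06
1790,1.02816e-06
1800,9.49141e-07
1810,8.74814e-07
1820,8.04981e-07
1830,7.39452e-07
1840,6.78042e-07
1850,6.20569e-07
1860,5.66858e-07
1870,5.16736e-07
1880,4.70037e-07
1890,4.26597e-07
1900,3.86258e-07
1910,3.48867e-07
1920,3.14273e-07
1930,2.8233e-07
1940,2.52898e-07
1950,2.2584e-07
1960,2.01023e-07
1970,1.78317e-07
1980,1.57598e-07
1990,1.38746e-07
2000,1.21643e-07
2010,1.06176e-07
2020,9.22379e-08
2030,7.97223e-08
2040,6.85287e-08
2050,5.85598e-08
2060,4.97224e-08
2070,4.19267e-08
2080,3.50872e-08
2090,2.9122e-08
2100,2.39527e-08
2110,1.9505e-08
2120,1.57081e-08
2130,1.2495e-08
2140,9.8024e-09
2150,7.57069e-09
2160,5.74388e-09
2170,4.26967e-09
2180,3.0994e-09
2190,2.18806e-09
2200,1.49427e-09
2210,9.80258e-10
2220,6.1189e-10
2230,3.5863e-10
2240,1.93551e-10
2250,9.33231e-11
2260,3.82145e-11
2270,1.20849e-11
2280,2.38377e-12
2290,1.47864e-13
2300,0
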