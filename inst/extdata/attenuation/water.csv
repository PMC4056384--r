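energy_keV,mu_over_rho_total,mu_over_rho_pe,mu_over_rho_incoh
30,0.29986,0.100128,0.199732
33.020825,0.2754825,0.0777025,0.19778
36.34583,0.2559909,0.0602999,0.195691
40.005643,0.2402538,0.0467948,0.193459
44.033978,0.2273954,0.0363144,0.191081
48.467943,0.2167353,0.0281813,0.188554
53.348382,0.2077467,0.0218697,0.185877
58.720253,0.2000196,0.0169716,0.183048
64.633041,0.1932396,0.0131706,0.180069
71.141211,0.1871618,0.0102208,0.176941
78.304716,0.18160074,0.00793174,0.173669
86.189545,0.17641331,0.00615531,0.170258
94.86833,0.17149273,0.00477673,0.166716
104.42102,0.16675691,0.00370691,0.16305
114.93561,0.1621467,0.0028767,0.15927
126.50895,0.15762242,0.00223242,0.15539
139.24767,0.15315244,0.00173244,0.15142
153.26909,0.14871809,0.00134309,0.147375
168.7024,0.14430666,0.00103766,0.143269
185.68975,0.139917689,0.000801689,0.139116
204.38762,0.135551637,0.000619637,0.134932
224.96826,0.131209607,0.000479607,0.13073
247.62126,0.126895222,0.000371222,0.126524
272.55527,0.122615331,0.000287331,0.122328
300,0.118374398,0.000222398,0.118152
330.20825,0.1141826,0.0001736,0.114009
363.4583,0.110042509,0.000135509,0.109907
400.05643,0.105960777,0.000105777,0.105855
440.33978,0.1019423927,8.33927e-05,0.101859
484.67943,0.0979908454,6.57454e-05,0.0979251
533.48382,0.0941106672,5.21672e-05,0.0940585
587.20253,0.0903041213,4.15213e-05,0.0902626
646.33041,0.0865741698,3.33698e-05,0.0865408
711.41211,0.082922194,2.6894e-05,0.0828953
783.04716,0.0793500749,2.16749e-05,0.0793284
861.89545,0.0758594542,1.76542e-05,0.0758418
948.6833,0.0724516231,1.44231e-05,0.0724372
1044.2102,0.0691277834,1.17834e-05,0.069116
1149.3561,0.06588942673,9.62673e-06,0.0658798
1265.0895,0.06273776482,7.86482e-06,0.0627299
1392.4767,0.05967422538,6.42538e-06,0.0596678
1532.6909,0.05669994939,5.24939e-06,0.0566947
1687.024,0.05381648863,4.28863e-06,0.0538122
1856.8975,0.05102480371,3.50371e-06,0.0510213
2043.8762,0.04832606245,2.86245e-06,0.0483232
2249.6826,0.04572103856,2.33856e-06,0.0457187
2476.2126,0.04321051055,1.91055e-06,0.0432086
2725.5527,0.04079486088,1.56088e-06,0.0407933
3000,0.0384742752,1.2752e-06,0.038473
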