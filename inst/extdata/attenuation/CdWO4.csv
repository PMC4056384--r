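energy_keV,mu_over_rho_total,mu_over_rho_pe,mu_over_rho_incoh
30,16.567917,16.4141,0.153817
33.020825,12.890314,12.738,0.152314
36.34583,10.035805,9.8851,0.150705
40.005643,7.820176,7.67119,0.148986
44.033978,6.100265,5.95311,0.147155
48.467943,4.765029,4.61982,0.145209
53.348382,3.728297,3.58515,0.143147
58.720253,2.923169,2.7822,0.140969
64.633041,2.297764,2.15909,0.138674
69.518048,1.917765,1.78091,0.136855
69.531952,5.94368,5.80683,0.13685
71.141211,5.602366,5.4661,0.136266
78.304716,4.375636,4.24189,0.133746
86.189545,3.422969,3.29185,0.131119
94.86833,2.682981,2.55459,0.128391
104.42102,2.108018,1.98245,0.125568
114.93561,1.661107,1.53845,0.122657
126.50895,1.313569,1.1939,0.119669
139.24767,1.043116,0.926505,0.116611
153.26909,0.831778,0.718282,0.113496
168.7024,0.665274,0.55494,0.110334
185.68975,0.535879,0.428743,0.107136
204.38762,0.435294,0.331381,0.103913
224.96826,0.35717,0.256493,0.100677
247.62126,0.2959676,0.198529,0.0974386
272.55527,0.2478708,0.153664,0.0942068
300,0.2099294,0.118938,0.0909914
330.20825,0.1806414,0.0928409,0.0878005
363.4583,0.1571113,0.0724698,0.0846415
400.05643,0.1380901,0.0565694,0.0815207
440.33978,0.1230417,0.0445983,0.0784434
484.67943,0.1105746,0.0351606,0.075414
533.48382,0.1003352,0.027899,0.0724362
587.20253,0.0917186,0.0222056,0.069513
646.33041,0.0844928,0.0178461,0.0666467
711.41211,0.0782222,0.0143829,0.0638393
783.04716,0.072684,0.0115917,0.0610923
861.89545,0.06784877,0.00944147,0.0584073
948.6833,0.06349877,0.00771347,0.0557853
1044.2102,0.05952933,0.00630173,0.0532276
1149.3561,0.05588367,0.00514837,0.0507353
1265.0895,0.0525156,0.0042061,0.0483095
1392.4767,0.04938759,0.00343629,0.0459513
1532.6909,0.04646907,0.00280737,0.0436617
1687.024,0.04373536,0.00229356,0.0414418
1856.8975,0.04116628,0.00187378,0.0392925
2043.8762,0.03874544,0.00153084,0.0372146
2249.6826,0.03645956,0.00125066,0.0352089
2476.2126,0.03429756,0.00102176,0.0332758
2725.5527,0.032250455,0.000834755,0.0314157
3000,0.030310776,0.000681976,0.0296288
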