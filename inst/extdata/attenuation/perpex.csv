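energy_keV,mu_over_rho_total,mu_over_rho_pe,mu_over_rho_incoh
30,0.2578065,0.0637325,0.194074
33.020825,0.2416367,0.0494587,0.192178
36.34583,0.2285287,0.0383817,0.190147
40.005643,0.2177645,0.0297855,0.187979
44.033978,0.2087826,0.0231146,0.185668
48.467943,0.2011508,0.0179378,0.183213
53.348382,0.1945313,0.0139203,0.180611
58.720253,0.1886647,0.0108027,0.177862
64.633041,0.18335125,0.00838325,0.174968
71.141211,0.1784347,0.0065057,0.171929
78.304716,0.17379865,0.00504865,0.16875
86.189545,0.16935293,0.00391793,0.165435
94.86833,0.16503345,0.00304045,0.161993
104.42102,0.1607905,0.0023595,0.158431
114.93561,0.15659005,0.00183105,0.154759
126.50895,0.15240896,0.00142096,0.150988
139.24767,0.14823272,0.00110272,0.14713
153.26909,0.144054893,0.000854893,0.1432
168.7024,0.139870484,0.000660484,0.13921
185.68975,0.135685286,0.000510286,0.135175
204.38762,0.131503407,0.000394407,0.131109
224.96826,0.127331276,0.000305276,0.127026
247.62126,0.123176288,0.000236288,0.12294
272.55527,0.11904489,0.00018289,0.118862
300,0.114946559,0.000141559,0.114805
330.20825,0.110889498,0.000110498,0.110779
363.4583,0.1068802529,8.62529e-05,0.106794
400.05643,0.1029233284,6.73284e-05,0.102856
440.33978,0.0990263805,5.30805e-05,0.0989733
484.67943,0.0951929478,4.18478e-05,0.0951511
533.48382,0.0914272051,3.32051e-05,0.091394
587.20253,0.0877321289,2.64289e-05,0.0877057
646.33041,0.0841104403,2.12403e-05,0.0840892
711.41211,0.0805642184,1.71184e-05,0.0805471
783.04716,0.0770949964,1.37964e-05,0.0770812
861.89545,0.0737046372,1.12372e-05,0.0736934
948.6833,0.0703943805,9.1805e-06,0.0703852
1044.2102,0.06716560026,7.50026e-06,0.0671581
1149.3561,0.06401972754,6.12754e-06,0.0640136
1265.0895,0.06095790606,5.00606e-06,0.0609529
1392.4767,0.05798158984,4.08984e-06,0.0579775
1532.6909,0.0550920413,3.3413e-06,0.0550887
1687.024,0.05229052977,2.72977e-06,0.0522878
1856.8975,0.04957823016,2.23016e-06,0.049576
2043.8762,0.04695612199,1.82199e-06,0.0469543
2249.6826,0.04442508852,1.48852e-06,0.0444236
2476.2126,0.04198581609,1.21609e-06,0.0419846
2725.5527,0.039638693518,9.93518e-07,0.0396377
3000,0.037384011681,8.11681e-07,0.0373832
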