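energy_keV,mu_over_rho_total,mu_over_rho_pe,mu_over_rho_incoh
30,23.015,22.8726,0.1424
33.020825,17.890908,17.7499,0.141008
36.34583,13.914118,13.7746,0.139518
40.005643,10.827427,10.6895,0.137927
44.033978,8.431692,8.29546,0.136232
48.467943,6.572,6.43757,0.13443
53.348382,5.128301,4.99578,0.132521
58.720253,4.007404,3.8769,0.130504
64.633041,3.13699,3.00861,0.12838
71.141211,2.460941,2.33479,0.126151
78.304716,1.935698,1.81188,0.123818
86.189545,1.527466,1.40608,0.121386
87.9962,1.451918,1.33107,0.120848
88.0138,7.171783,7.05094,0.120843
94.86833,5.90206,5.7832,0.11886
104.42102,4.604207,4.48796,0.116247
114.93561,3.596372,3.48282,0.113552
126.50895,2.813576,2.70279,0.110786
139.24767,2.205415,2.09746,0.107955
153.26909,1.731151,1.62608,0.105071
168.7024,1.358444,1.2563,0.102144
185.68975,1.0697892,0.970606,0.0991832
204.38762,0.8463949,0.750195,0.0961999
224.96826,0.6738651,0.580661,0.0932041
247.62126,0.5396447,0.449439,0.0902057
272.55527,0.4350858,0.347872,0.0872138
300,0.3534941,0.269257,0.0842371
330.20825,0.2914601,0.210177,0.0812831
363.4583,0.2424185,0.16406,0.0783585
400.05643,0.2035334,0.128064,0.0754694
440.33978,0.1735845,0.100964,0.0726205
484.67943,0.149414,0.079598,0.069816
533.48382,0.1302181,0.0631588,0.0670593
587.20253,0.1146229,0.0502699,0.064353
646.33041,0.1021003,0.0404008,0.0616995
711.41211,0.0916611,0.0325606,0.0591005
783.04716,0.0827993,0.0262419,0.0565574
861.89545,0.0754457,0.021374,0.0540717
948.6833,0.0691064,0.0174621,0.0516443
1044.2102,0.0635426,0.0142661,0.0492765
1149.3561,0.0586243,0.0116551,0.0469692
1265.0895,0.05424544,0.00952194,0.0447235
1392.4767,0.05031951,0.00777921,0.0425403
1532.6909,0.04677614,0.00635544,0.0404207
1687.024,0.04355785,0.00519225,0.0383656
1856.8975,0.04061775,0.00424195,0.0363758
2043.8762,0.03791778,0.00346558,0.0344522
2249.6826,0.0354266,0.0028313,0.0325953
2476.2126,0.0331188,0.0023131,0.0308057
2725.5527,0.03097345,0.00188975,0.0290837
3000,0.02897339,0.00154389,0.0274295
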