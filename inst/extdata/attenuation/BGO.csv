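energy_keV,mu_over_rho_total,mu_over_rho_pe,mu_over_rho_incoh
30,17.442337,17.291,0.151337
33.020825,13.568358,13.4185,0.149858
36.34583,10.561475,10.4132,0.148275
40.005643,8.227594,8.08101,0.146584
44.033978,6.415932,6.27115,0.144782
48.467943,5.009498,4.86663,0.142868
53.348382,3.917519,3.77668,0.140839
58.720253,3.069526,2.93083,0.138696
64.633041,2.410868,2.27443,0.136438
71.141211,1.899109,1.76504,0.134069
78.304716,1.50132,1.36973,0.13159
86.189545,1.191965,1.06296,0.129005
90.516947,1.061524,0.933877,0.127647
90.535053,4.774171,4.64653,0.127641
94.86833,4.232781,4.10646,0.126321
104.42102,3.310303,3.18676,0.123543
114.93561,2.59372,2.47304,0.12068
126.50895,2.036899,1.91916,0.117739
139.24767,1.604071,1.48934,0.114731
153.26909,1.266286,1.15462,0.111666
168.7024,1.00061,0.892055,0.108555
185.68975,0.794603,0.689195,0.105408
204.38762,0.634927,0.532689,0.102238
224.96826,0.5113621,0.412308,0.0990541
247.62126,0.4149995,0.319132,0.0958675
272.55527,0.3396998,0.247012,0.0926878
300,0.2807152,0.191191,0.0895242
330.20825,0.2356248,0.14924,0.0863848
363.4583,0.1997708,0.116494,0.0832768
400.05643,0.1711404,0.0909342,0.0802062
440.33978,0.1488695,0.071691,0.0771785
484.67943,0.1307179,0.0565199,0.074198
533.48382,0.1161153,0.044847,0.0712683
587.20253,0.1040872,0.035695,0.0683922
646.33041,0.0942594,0.0286873,0.0655721
711.41211,0.0859301,0.0231202,0.0628099
783.04716,0.0787408,0.0186335,0.0601073
861.89545,0.0726425,0.015177,0.0574655
948.6833,0.067285,0.0123992,0.0548858
1044.2102,0.0624993,0.0101299,0.0523694
1149.3561,0.0581931,0.0082759,0.0499172
1265.0895,0.05429182,0.00676122,0.0475306
1392.4767,0.05073416,0.00552376,0.0452104
1532.6909,0.04747049,0.00451279,0.0429577
1687.024,0.04446045,0.00368685,0.0407736
1856.8975,0.04167097,0.00301207,0.0386589
2043.8762,0.03907539,0.00246079,0.0366146
2249.6826,0.03665151,0.00201041,0.0346411
2476.2126,0.03438166,0.00164246,0.0327392
2725.5527,0.03225105,0.00134185,0.0309092
3000,0.03024736,0.00109626,0.0291511
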