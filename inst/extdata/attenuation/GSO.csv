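energy_keV,mu_over_rho_total,mu_over_rho_pe,mu_over_rho_incoh
30,8.337691,8.18272,0.154971
33.020825,6.503537,6.35008,0.153457
36.34583,5.079715,4.92788,0.151835
40.005643,3.974314,3.82421,0.150104
44.033978,3.115979,2.96772,0.148259
48.467943,2.449358,2.30306,0.146298
50.233976,2.240747,2.09521,0.145537
50.244024,11.174233,11.0287,0.145533
53.348382,9.556861,9.41264,0.144221
58.720253,7.446566,7.30454,0.142026
64.633041,5.808294,5.66858,0.139714
71.141211,4.536308,4.39902,0.137288
78.304716,3.548539,3.41379,0.134749
86.189545,2.781323,2.64922,0.132103
94.86833,2.185244,2.05589,0.129354
104.42102,1.721949,1.59544,0.126509
114.93561,1.361697,1.23812,0.123577
126.50895,1.081391,0.960825,0.120566
139.24767,0.86312,0.745634,0.117486
153.26909,0.692408,0.578061,0.114347
168.7024,0.557767,0.446606,0.111161
185.68975,0.452983,0.345044,0.107939
204.38762,0.371383,0.26669,0.104693
224.96826,0.307853,0.206421,0.101432
247.62126,0.2579423,0.159773,0.0981693
272.55527,0.2185793,0.123666,0.0949133
300,0.1873932,0.0957194,0.0916738
330.20825,0.1631757,0.0747167,0.088459
363.4583,0.1435987,0.0583224,0.0852763
400.05643,0.127658,0.045526,0.082132
440.33978,0.1149235,0.0358919,0.0790316
484.67943,0.1042762,0.0282966,0.0759796
533.48382,0.0954321,0.0224526,0.0729795
587.20253,0.0879049,0.0178706,0.0700343
646.33041,0.0815087,0.0143622,0.0671465
711.41211,0.0758931,0.0115751,0.064318
783.04716,0.07087932,0.00932882,0.0615505
861.89545,0.06644363,0.00759833,0.0588453
948.6833,0.06241126,0.00620766,0.0562036
1044.2102,0.05869832,0.00507152,0.0536268
1149.3561,0.05525911,0.00414331,0.0511158
1265.0895,0.05205679,0.00338499,0.0486718
1392.4767,0.04906136,0.00276546,0.0462959
1532.6909,0.04624852,0.00225932,0.0439892
1687.024,0.04359841,0.00184581,0.0417526
1856.8975,0.04109519,0.00150799,0.0395872
2043.8762,0.03872569,0.00123199,0.0374937
2249.6826,0.03647941,0.00100651,0.0354729
2476.2126,0.034347594,0.000822294,0.0335253
2725.5527,0.032323096,0.000671796,0.0316513
3000,0.030399842,0.000548842,0.029851
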