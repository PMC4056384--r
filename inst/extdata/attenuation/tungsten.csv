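energy_keV,mu_over_rho_total,mu_over_rho_pe,mu_over_rho_incoh
30,17.067836,16.923,0.144836
33.020825,13.276321,13.1329,0.143421
36.34583,10.333505,10.1916,0.141905
40.005643,8.049297,7.90901,0.140287
44.033978,6.276233,6.13767,0.138563
48.467943,4.89978,4.76305,0.13673
53.348382,3.831079,3.69629,0.134789
58.720253,3.001187,2.86845,0.132737
64.633041,2.356597,2.22602,0.130577
69.518048,1.964984,1.83612,0.128864
69.531952,9.85517,9.72631,0.12886
71.141211,9.283909,9.1556,0.128309
78.304716,7.231006,7.10507,0.125936
86.189545,5.637243,5.51378,0.123463
94.86833,4.399784,4.27889,0.120894
104.42102,3.438806,3.32057,0.118236
114.93561,2.692375,2.57688,0.115495
126.50895,2.112431,1.99975,0.112681
139.24767,1.661682,1.55188,0.109802
153.26909,1.309979,1.20311,0.106869
168.7024,1.033403,0.929512,0.103891
185.68975,0.819014,0.718134,0.10088
204.38762,0.6529018,0.555056,0.0978458
224.96826,0.5244197,0.429621,0.0947987
247.62126,0.424281,0.332532,0.091749
272.55527,0.34609,0.257384,0.088706
300,0.2848973,0.199219,0.0856783
330.20825,0.2381807,0.155507,0.0826737
363.4583,0.2010842,0.121385,0.0796992
400.05643,0.1715131,0.0947525,0.0767606
440.33978,0.1485642,0.0747012,0.073863
484.67943,0.1299037,0.0588932,0.0710105
533.48382,0.1149367,0.0467301,0.0682066
587.20253,0.1026479,0.0371938,0.0654541
646.33041,0.092647,0.0298919,0.0627551
711.41211,0.0842026,0.024091,0.0601116
783.04716,0.076941,0.0194159,0.0575251
861.89545,0.0708111,0.0158143,0.0549968
948.6833,0.0654478,0.0129199,0.0525279
1044.2102,0.0606749,0.0105553,0.0501196
1149.3561,0.0563962,0.0086234,0.0477728
1265.0895,0.05253382,0.00704512,0.0454887
1392.4767,0.04902381,0.00575571,0.0432681
1532.6909,0.04581458,0.00470228,0.0411123
1687.024,0.04286366,0.00384166,0.039022
1856.8975,0.04013675,0.00313855,0.0369982
2043.8762,0.03760572,0.00256412,0.0350416
2249.6826,0.03524783,0.00209483,0.033153
2476.2126,0.03304423,0.00171143,0.0313328
2725.5527,0.0309795,0.0013982,0.0295813
3000,0.02904109,0.00114229,0.0278988
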