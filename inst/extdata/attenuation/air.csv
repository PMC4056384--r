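energy_keV,mu_over_rho_total,mu_over_rho_pe,mu_over_rho_incoh
30,0.2782818,0.0986688,0.179613
33.020825,0.2544285,0.0765705,0.177858
36.34583,0.2354004,0.0594214,0.175979
40.005643,0.2200851,0.0461131,0.173972
44.033978,0.2076194,0.0357854,0.171834
48.467943,0.1973317,0.0277707,0.169561
53.348382,0.1887041,0.0215511,0.167153
58.720253,0.1813344,0.0167244,0.16461
64.633041,0.1749087,0.0129787,0.16193
71.141211,0.1691899,0.0100719,0.159118
78.304716,0.16399218,0.00781618,0.156176
86.189545,0.15917463,0.00606563,0.153109
94.86833,0.15463014,0.00470714,0.149923
104.42102,0.15027891,0.00365291,0.146626
114.93561,0.14606179,0.00283479,0.143227
126.50895,0.14193689,0.00219989,0.139737
139.24767,0.1378752,0.0017072,0.136168
153.26909,0.13385352,0.00132352,0.13253
168.7024,0.12985954,0.00102254,0.128837
185.68975,0.125893009,0.000790009,0.125103
204.38762,0.121950609,0.000610609,0.12134
224.96826,0.11803362,0.00047262,0.117561
247.62126,0.114144814,0.000365814,0.113779
272.55527,0.110289145,0.000283145,0.110006
300,0.106470158,0.000219158,0.106251
330.20825,0.10269607,0.00017107,0.102525
363.4583,0.098969734,0.000133534,0.0988362
400.05643,0.095296236,0.000104236,0.095192
440.33978,0.0916807777,8.21777e-05,0.0915986
484.67943,0.0881259875,6.47875e-05,0.0880612
533.48382,0.0846355071,5.14071e-05,0.0845841
587.20253,0.0812115164,4.09164e-05,0.0811706
646.33041,0.0778564836,3.28836e-05,0.0778236
711.41211,0.0745719022,2.65022e-05,0.0745454
783.04716,0.0713591592,2.13592e-05,0.0713378
861.89545,0.068219797,1.7397e-05,0.0682024
948.6833,0.065154913,1.4213e-05,0.0651407
1044.2102,0.0621657117,1.16117e-05,0.0621541
1149.3561,0.05925328648,9.48648e-06,0.0592438
1265.0895,0.05641895024,7.75024e-06,0.0564112
1392.4767,0.05366383177,6.33177e-06,0.0536575
1532.6909,0.05098917291,5.17291e-06,0.050984
1687.024,0.04839602615,4.22615e-06,0.0483918
1856.8975,0.04588545267,3.45267e-06,0.045882
2043.8762,0.04345842075,2.82075e-06,0.0434556
2249.6826,0.04111580449,2.30449e-06,0.0411135
2476.2126,0.03885818272,1.88272e-06,0.0388563
2725.5527,0.03668583814,1.53814e-06,0.0366843
3000,0.03459895662,1.25662e-06,0.0345977
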