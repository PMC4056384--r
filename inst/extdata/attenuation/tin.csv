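energy_keV,mu_over_rho_total,mu_over_rho_pe,mu_over_rho_incoh
30,27.989254,27.8377,0.151554
33.020825,21.753073,21.603,0.150073
36.34583,16.913187,16.7647,0.148487
40.005643,13.156794,13.01,0.146794
44.033978,10.24119,10.0962,0.14499
48.467943,7.978102,7.83503,0.143072
53.348382,6.221301,6.08026,0.141041
58.720253,4.857384,4.71849,0.138894
64.633041,3.798354,3.66172,0.136634
71.141211,2.97588,2.84162,0.13426
78.304716,2.336978,2.2052,0.131778
86.189545,1.8405,1.71131,0.12919
94.86833,1.454542,1.32804,0.126502
104.42102,1.15432,1.0306,0.12372
114.93561,0.920638,0.799786,0.120852
126.50895,0.73857,0.620662,0.117908
139.24767,0.59655,0.481655,0.114895
153.26909,0.485234,0.373408,0.111826
168.7024,0.397203,0.288493,0.10871
185.68975,0.328446,0.222887,0.105559
204.38762,0.274657,0.172273,0.102384
224.96826,0.2325369,0.133341,0.0991959
247.62126,0.1992127,0.103208,0.0960047
272.55527,0.1727049,0.0798844,0.0928205
300,0.151484,0.0618316,0.0896524
330.20825,0.1347731,0.0482646,0.0865085
363.4583,0.1210703,0.0376744,0.0833959
400.05643,0.1097293,0.0294083,0.080321
440.33978,0.100474,0.023185,0.077289
484.67943,0.0925829,0.0182787,0.0743042
533.48382,0.0858739,0.0145036,0.0713703
587.20253,0.0800339,0.0115438,0.0684901
646.33041,0.07494354,0.00927754,0.065666
711.41211,0.07037693,0.00747713,0.0628998
783.04716,0.06621941,0.00602611,0.0601933
861.89545,0.06245597,0.00490827,0.0575477
948.6833,0.05897434,0.00400994,0.0549644
1044.2102,0.05572033,0.00327603,0.0524443
1149.3561,0.05266514,0.00267644,0.0499887
1265.0895,0.04978519,0.00218659,0.0475986
1392.4767,0.0470615,0.0017864,0.0452751
1532.6909,0.04447865,0.00145945,0.0430192
1687.024,0.04202433,0.00119233,0.040832
1856.8975,0.03968841,0.00097411,0.0387143
2043.8762,0.037462826,0.000795826,0.036667
2249.6826,0.035340872,0.000650172,0.0346907
2476.2126,0.033317275,0.000531175,0.0327861
2725.5527,0.031387358,0.000433958,0.0309534
3000,0.029547334,0.000354534,0.0291928
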