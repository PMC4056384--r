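energy_keV,mu_over_rho_total,mu_over_rho_pe,mu_over_rho_incoh
30,5.480062,5.32643,0.153632
33.020825,4.285631,4.1335,0.152131
33.165683,4.23802,4.08596,0.15206
33.172317,21.649857,21.4978,0.152057
36.34583,17.036623,16.8861,0.150523
40.005643,13.253007,13.1042,0.148807
44.033978,10.316278,10.1693,0.146978
48.467943,8.036774,7.89174,0.145034
53.348382,6.267245,6.12427,0.142975
58.720253,4.893449,4.75265,0.140799
64.633041,3.826727,3.68822,0.138507
71.141211,2.998291,2.86219,0.136101
78.304716,2.354745,2.22116,0.133585
86.189545,1.854661,1.7237,0.130961
94.86833,1.465886,1.33765,0.128236
104.42102,1.163486,1.03807,0.125416
114.93561,0.928084,0.805575,0.122509
126.50895,0.744679,0.625155,0.119524
139.24767,0.601613,0.485142,0.116471
153.26909,0.48947,0.376111,0.113359
168.7024,0.400782,0.290581,0.110201
185.68975,0.331508,0.224501,0.107007
204.38762,0.277308,0.17352,0.103788
224.96826,0.234863,0.134307,0.100556
247.62126,0.2012761,0.103955,0.0973211
272.55527,0.1745559,0.0804627,0.0940932
300,0.1531609,0.0622792,0.0908817
330.20825,0.1363086,0.0486139,0.0876947
363.4583,0.1224866,0.0379471,0.0845395
400.05643,0.1110436,0.0296212,0.0814224
440.33978,0.1017017,0.0233529,0.0783488
484.67943,0.0937341,0.018411,0.0753231
533.48382,0.0869575,0.0146086,0.0723489
587.20253,0.0810566,0.0116274,0.0694292
646.33041,0.0759111,0.0093447,0.0665664
711.41211,0.07129356,0.00753126,0.0637623
783.04716,0.06708844,0.00606974,0.0610187
861.89545,0.0632806,0.0049438,0.0583368
948.6833,0.05975697,0.00403897,0.055718
1044.2102,0.05646315,0.00329975,0.0531634
1149.3561,0.05336992,0.00269582,0.0506741
1265.0895,0.05045372,0.00220242,0.0482513
1392.4767,0.04769523,0.00179933,0.0458959
1532.6909,0.04507911,0.00147001,0.0436091
1687.024,0.04259277,0.00120097,0.0413918
1856.8975,0.040226262,0.000981162,0.0392451
2043.8762,0.037971287,0.000801587,0.0371697
2249.6826,0.035821278,0.000654878,0.0351664
2476.2126,0.03377072,0.00053502,0.0332357
2725.5527,0.0318149,0.0004371,0.0313778
3000,0.0299502,0.0003571,0.0295931
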