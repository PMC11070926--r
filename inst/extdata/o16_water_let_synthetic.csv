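# Synthetic energy-LET table for 16-O ions in liquid water (unit density).
# Computed from the Bethe stopping-power formula with Barkas effective-charge
# scaling, I = 75 eV, Z/A = 0.5551; NOT a measured/ICRU table. Accuracy a few
# percent for E > 5 MeV/u, adequate for effective amorphous-track models.
# Columns: energy_mev_u (MeV per nucleon), let_kev_um (keV per micrometre).
energy_mev_u,let_kev_um
5,470.1561
5.399,446.6728
5.83,423.903
6.295,401.9056
6.798,380.6498
7.34,360.2358
7.926,340.6056
8.559,321.7868
9.242,303.8009
9.979,286.6402
10.776,270.261
11.636,254.6883
12.565,239.8887
13.567,225.8649
14.65,212.5663
15.82,199.9781
17.082,188.0943
18.446,176.8645
19.918,166.2791
21.507,156.3067
23.224,146.9102
25.077,138.0739
27.079,129.7606
29.24,121.9512
31.574,114.6147
34.094,107.7282
36.815,101.2665
39.753,95.2058
42.926,89.5222
46.352,84.1952
50.052,79.203
54.046,74.5283
58.36,70.1493
63.018,66.0501
68.047,62.2141
73.478,58.6244
79.343,55.2663
85.675,52.1266
92.513,49.1911
99.897,46.4475
107.87,43.8844
116.479,41.4906
125.776,39.2555
135.814,37.1697
146.654,35.2237
158.359,33.4091
170.998,31.7178
184.645,30.1422
199.382,28.6752
215.295,27.3102
232.479,26.0408
251.033,24.8614
271.069,23.7662
292.703,22.7504
316.065,21.8089
341.291,20.9375
368.53,20.1317
397.943,19.3877
429.704,18.7018
463.999,18.0705
501.032,17.4906
541.021,16.959
584.201,16.4729
630.827,16.0297
681.175,15.6267
735.541,15.2617
794.246,14.9325
857.637,14.6369
926.087,14.373
1000,14.139
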