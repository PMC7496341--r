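# linear attenuation coefficient, water
# columns: energy_keV  mu_per_cm
10 5.31834
12 3.15886
14 2.03349
16 1.41876
18 1.05402
20 0.807981
23 0.620054
26 0.491557
30 0.374849
34 0.32381
38 0.284316
42 0.258129
46 0.241081
50 0.226446
55 0.215237
60 0.205488
65 0.199068
70 0.193303
75 0.188085
80 0.183333
85 0.179713
90 0.176366
95 0.173257
100 0.170359
110 0.165389
120 0.160979
130 0.157026
140 0.153453
150 0.150199
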