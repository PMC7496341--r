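# linear attenuation coefficient, iron
# columns: energy_keV  mu_per_cm
10 1343.3
12 821.038
14 541.487
16 375.715
18 270.916
20 202.204
23 136.288
26 96.4188
30 64.3778
34 45.2129
38 33.0277
42 24.9684
46 19.4152
50 15.4173
55 11.9618
60 9.48817
65 7.79746
70 6.50194
75 5.49008
80 4.6866
85 4.12389
90 3.65537
95 3.26129
100 2.92677
110 2.5192
120 2.19689
130 1.93694
140 1.72377
150 1.54645
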