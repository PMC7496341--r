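# linear attenuation coefficient, bone
# columns: energy_keV  mu_per_cm
10 54.7392
12 32.6454
14 21.0877
16 14.4463
18 10.3509
20 7.68192
23 5.25665
26 3.76857
30 2.55552
34 1.8902
38 1.44585
42 1.15794
46 0.963725
50 0.814464
55 0.696877
60 0.604416
65 0.549063
70 0.502343
75 0.462429
80 0.427968
85 0.407137
90 0.388426
95 0.371519
100 0.35616
110 0.337745
120 0.321767
130 0.307737
140 0.295292
150 0.28416
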