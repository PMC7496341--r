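# 120 kVp tungsten spectrum, filtered Kramers model + K lines
# columns: energy_keV  relative_fluence (normalized to sum 1)
10 6.10004753e-10
11 4.58317693e-08
12 9.30682998e-07
13 8.09152336e-06
14 3.97958874e-05
15 1.31959153e-04
16 3.27956397e-04
17 6.67304064e-04
18 1.17057111e-03
19 1.83589295e-03
20 2.64261375e-03
21 3.50194333e-03
22 4.42390581e-03
23 5.37826284e-03
24 6.33847943e-03
25 7.28281940e-03
26 8.19451193e-03
27 9.06137334e-03
28 9.87516647e-03
29 1.06308813e-02
30 1.13260425e-02
31 1.18592934e-02
32 1.23428928e-02
33 1.27786542e-02
34 1.31687334e-02
35 1.35154898e-02
36 1.38213822e-02
37 1.40888927e-02
38 1.43204715e-02
39 1.45184992e-02
40 1.46852605e-02
41 1.47652832e-02
42 1.48248212e-02
43 1.48652493e-02
44 1.48878477e-02
45 1.48938069e-02
46 1.48842333e-02
47 1.48601541e-02
48 1.48225227e-02
49 1.47722236e-02
50 1.47100777e-02
51 1.46087689e-02
52 1.44998334e-02
53 1.43837113e-02
54 1.42608122e-02
55 1.41315176e-02
56 1.39961833e-02
57 1.38551414e-02
58 3.77087016e-02
59 4.95571537e-02
60 1.34007685e-02
61 1.32224466e-02
62 1.30412364e-02
63 1.28572676e-02
64 1.26706627e-02
65 1.24815370e-02
66 1.22899993e-02
67 2.64961524e-02
68 1.19000934e-02
69 1.73019142e-02
70 1.15017017e-02
71 1.12995383e-02
72 1.10955021e-02
73 1.08896669e-02
74 1.06821032e-02
75 1.04728775e-02
76 1.02620532e-02
77 1.00496906e-02
78 9.83584706e-03
79 9.62057702e-03
80 9.40393248e-03
81 9.18054141e-03
82 8.95631915e-03
83 8.73129102e-03
84 8.50548125e-03
85 8.27891310e-03
86 8.05160884e-03
87 7.82358988e-03
88 7.59487675e-03
89 7.36548916e-03
90 7.13544608e-03
91 6.90476571e-03
92 6.67346558e-03
93 6.44156255e-03
94 6.20907283e-03
95 5.97601206e-03
96 5.74239527e-03
97 5.50823697e-03
98 5.27355114e-03
99 5.03835127e-03
100 4.80265034e-03
101 4.56524518e-03
102 4.32751576e-03
103 4.08946909e-03
104 3.85111200e-03
105 3.61245107e-03
106 3.37349271e-03
107 3.13424309e-03
108 2.89470824e-03
109 2.65489396e-03
110 2.41480593e-03
111 2.17444961e-03
112 1.93383034e-03
113 1.69295327e-03
114 1.45182344e-03
115 1.21044572e-03
116 9.68824836e-04
117 7.26965408e-04
118 4.84871910e-04
119 2.42548695e-04
120 0.00000000e+00
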