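age,qx
40,0.00132
41,0.001429
42,0.001546
43,0.001673
44,0.001811
45,0.00196
46,0.002128
47,0.002311
48,0.00251
49,0.002726
50,0.00296
51,0.003207
52,0.003475
53,0.003765
54,0.004079
55,0.00442
56,0.004777
57,0.005164
58,0.005581
59,0.006032
60,0.00652
61,0.007055
62,0.007633
63,0.00826
64,0.008937
65,0.00967
66,0.010531
67,0.011468
68,0.012488
69,0.0136
70,0.01481
71,0.016204
72,0.017729
73,0.019397
74,0.021223
75,0.02322
76,0.025687
77,0.028416
78,0.031435
79,0.034775
80,0.03847
81,0.042811
82,0.047642
83,0.053019
84,0.059002
85,0.06566
86,0.073526
87,0.082334
88,0.092197
89,0.103242
90,0.11561
91,0.127702
92,0.141058
93,0.155812
94,0.172109
95,0.19011
96,0.205733
97,0.222639
98,0.240935
99,0.260734
100,0.28216
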