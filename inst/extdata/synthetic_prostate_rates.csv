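age,population,cancer_cases,cancer_deaths,all_cause_deaths
35,1e+05,18,4,114
36,99890,19,4,124
37,99770,21,4,135
38,99639,24,5,149
39,99495,26,5,162
40,99338,29,6,177
41,99167,32,6,193
42,98980,35,7,211
43,98776,39,8,231
44,98553,43,9,253
45,98310,47,9,275
46,98044,52,10,300
47,97754,57,11,328
48,97438,63,13,358
49,97093,69,14,391
50,96717,76,15,425
51,96308,84,17,464
52,95862,93,19,506
53,95376,102,20,550
54,94847,112,22,599
55,94272,123,25,652
56,93647,135,27,709
57,92968,148,30,771
58,92230,162,32,836
59,91429,178,36,908
60,90562,195,39,984
61,89621,213,43,1066
62,88604,232,46,1153
63,87504,254,51,1247
64,86315,277,55,1346
65,85034,301,60,1452
66,83653,327,65,1563
67,82168,355,71,1681
68,80574,385,77,1805
69,78865,417,83,1933
70,77036,450,90,2067
71,75084,485,97,2206
72,73004,521,104,2348
73,70795,558,112,2493
74,68454,596,119,2638
75,65981,635,127,2783
76,63377,610,122,2914
77,60646,584,117,3040
78,57793,556,111,3159
79,54824,528,106,3270
80,51750,498,100,3367
81,48584,468,94,3450
82,45341,437,87,3514
83,42040,405,81,3558
84,38703,373,75,3577
85,35354,340,68,3569
86,32021,308,62,3531
87,28733,277,55,3461
88,25521,246,49,3359
89,22416,216,43,3224
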