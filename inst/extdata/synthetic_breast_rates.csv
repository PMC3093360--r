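age,population,cancer_cases,cancer_deaths,all_cause_deaths
35,1e+05,144,29,99
36,99930,149,30,107
37,99853,154,31,115
38,99769,159,32,124
39,99677,165,33,134
40,99577,170,34,144
41,99466,176,35,156
42,99345,182,36,168
43,99213,188,38,183
44,99068,195,39,198
45,98910,201,40,214
46,98736,208,42,232
47,98546,215,43,251
48,98338,222,44,272
49,98111,230,46,295
50,97862,237,47,319
51,97590,245,49,347
52,97293,253,51,376
53,96968,261,52,408
54,96613,270,54,442
55,96226,278,56,480
56,95802,287,57,520
57,95341,296,59,564
58,94837,304,61,612
59,94288,314,63,663
60,93689,323,65,719
61,93037,332,66,778
62,92328,341,68,843
63,91556,350,70,912
64,90718,359,72,987
65,89807,368,74,1067
66,88819,377,75,1152
67,87749,386,77,1244
68,86590,395,79,1341
69,85337,403,81,1445
70,83984,410,82,1553
71,82526,403,81,1666
72,80956,396,79,1784
73,79269,387,77,1907
74,77459,378,76,2037
75,75523,369,74,2170
76,73456,359,72,2307
77,71255,348,70,2447
78,68917,337,67,2588
79,66442,325,65,2729
80,63830,312,62,2868
81,61085,298,60,3004
82,58211,284,57,3133
83,55215,270,54,3253
84,52107,255,51,3361
85,48900,239,48,3453
86,45610,223,45,3527
87,42258,206,41,3578
88,38864,190,38,3605
89,35456,173,35,3602
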