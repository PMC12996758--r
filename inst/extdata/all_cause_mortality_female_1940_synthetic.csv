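age_start,age_end,rate_per_100000
50,50,260
51,51,283.9
52,52,310
53,53,338.6
54,54,369.7
55,55,403.7
56,56,440.8
57,57,481.4
58,58,525.7
59,59,574
60,60,626.8
61,61,684.5
62,62,747.5
63,63,816.2
64,64,891.3
65,65,973.3
66,66,1062.8
67,67,1160.6
68,68,1267.3
69,69,1383.9
70,70,1511.2
71,71,1650.2
72,72,1802.1
73,73,1967.8
74,74,2148.8
75,75,2346.5
76,76,2562.4
77,77,2798.1
78,78,3055.4
79,79,3336.5
80,80,3643.4
81,81,3978.6
82,82,4344.6
83,83,4744.2
84,84,5180.6
85,85,5657.2
86,86,6177.6
87,87,6745.8
88,88,7366.4
89,89,8044
90,90,8784
91,91,9592
92,92,10474.3
93,93,11437.8
94,94,12490
95,95,13638.9
96,96,14893.5
97,97,16263.5
98,98,17759.6
99,99,19393.3
100,100,21177.2
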