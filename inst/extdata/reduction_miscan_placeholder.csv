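age,reduction
50,0.00
52,0.08
54,0.18
56,0.27
58,0.32
60,0.34
62,0.35
64,0.35
66,0.35
68,0.35
70,0.34
72,0.32
74,0.29
76,0.26
78,0.22
80,0.18
82,0.13
84,0.08
85,0.05
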