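age_start,age_end,rate_per_100000
50,54,40
55,59,56
60,64,73
65,69,76
70,74,102
75,79,115
80,85,142
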