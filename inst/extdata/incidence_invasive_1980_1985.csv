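age_start,age_end,rate_per_100000
50,54,120
55,59,133
60,64,163
65,69,197
70,74,223
75,79,256
80,85,265
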