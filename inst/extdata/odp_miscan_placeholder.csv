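age,odp
50,0.037
52,0.036
54,0.040
56,0.045
58,0.051
60,0.058
62,0.065
64,0.073
66,0.081
68,0.089
69,0.089
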