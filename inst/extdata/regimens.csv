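regimen,cumulative_harm_10y,proportion_overdiagnosed
BCT with or without radiation therapy,0.325,0.288
Mastectomy with or without radiation therapy,0.425,0.192
Surgery and hormonal therapy,0.575,0.32
Surgery and chemotherapy,0.510,0.12
"Surgery, hormonal therapy and chemotherapy",0.635,0.08
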