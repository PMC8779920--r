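regimen,route,dose_mg,n,age_y,weight_kg,height_m
iv_1500,iv_infusion,1500,24,23.71,64.19,1.70
oral_1500,oral,1500,24,23.71,64.19,1.70
oral_1000,oral,1000,8,33.8,57.4,1.612
oral_750,oral,750,8,21.0,58.8,1.653
oral_500,oral,500,8,21.0,58.8,1.653
oral_250,oral,250,8,21.0,58.8,1.653
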