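time_min,percent_dissolved
2.5,93.8
5,100
10,100
15,100
20,100
30,100
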