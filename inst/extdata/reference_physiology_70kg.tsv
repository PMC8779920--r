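tissue	volume_L	flow_fraction
lung	0.53	1.00
heart	0.33	0.04
brain	1.45	0.12
liver	1.82	0.065
kidney	0.31	0.19
muscle	26.0	0.12
adipose	13.5	0.05
skin	3.3	0.05
spleen	0.18	0.02
gut	1.65	0.16
rest_of_body	12.53	0.185
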