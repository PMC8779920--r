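tissue	f_water	f_neutral_lipid	f_phospholipid
lung	0.811	0.0030	0.0090
heart	0.758	0.0115	0.0166
brain	0.770	0.0510	0.0565
liver	0.751	0.0348	0.0252
kidney	0.783	0.0207	0.0162
muscle	0.760	0.0238	0.0072
adipose	0.180	0.7900	0.0020
skin	0.718	0.0284	0.0111
spleen	0.788	0.0201	0.0198
gut	0.718	0.0487	0.0163
rest_of_body	0.310	0.1500	0.0020
plasma	0.945	0.0035	0.00225
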