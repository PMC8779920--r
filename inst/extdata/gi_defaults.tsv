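name	radius_cm	transit_h	volume_L	ph
stomach	10.00	0.25	0.046	1.3
duodenum	1.60	0.26	0.042	6.0
jejunum1	1.50	0.95	0.154	6.2
jejunum2	1.34	0.76	0.122	6.4
ileum1	1.18	0.59	0.094	6.6
ileum2	1.01	0.43	0.071	6.9
ileum3	0.85	0.31	0.049	7.4
caecum	3.39	4.50	0.050	6.4
colon	2.42	13.00	0.050	6.8
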