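species	region	T	C	A	G
Liparis_chefuensis	PCGs	33.08	26.61	25.95	14.37
Liparis_chefuensis	rRNA	22.77	24.74	33.26	19.23
Liparis_chefuensis	tRNA	28.41	20.21	29.57	21.82
Liparis_chefuensis	control	31.94	13.71	43.25	11.10
Liparis_chefuensis	genome	30.16	24.79	30.75	14.30
Liparis_tanakae	PCGs	30.52	26.21	26.21	14.43
Liparis_tanakae	rRNA	22.72	24.32	32.48	20.48
Liparis_tanakae	tRNA	28.00	20.27	29.17	22.56
Liparis_tanakae	control	36.29	20.40	42.78	0.53
Liparis_tanakae	genome	27.77	28.10	29.64	14.49
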