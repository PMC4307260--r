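subgroup	pfam	gene_A	gene_B	rpkm_A_bud	rpkm_A_flower	rpkm_B_bud	aa_variation
II-2	PF03141	FLJSAMT59	rFLJSAM40	120.99	106.17	248.90	365A/E
II-8	PF03141	FLJSAMT53	rFLJSAMT30	495.65	860.77	0	275H/R, 289N/D, 441D/E, 623A/E
II-11	PF03141	FLJSAMT51	rFLJSAMT28	68.79	82.94	0	none
II-11	PF03141	FLJSAMT73	rFLJSAMT87	151.06	153.34	0	none
II-11	PF03141	FLJSAMT77	rFLJSAMT97	118.24	153.34	0	none
I-1	PF01135	FLJSAMT12	rFLJSAMT2	141.97	121.13	0	197V/I
I-1	PF02005	FLJSAMT36	rFLJSAMT45	77.75	54.43	0	49E/Q, 299L/S, 599V/A
I-1	PF02353	FLJSAMT37	rFLJSAMT24	52.42	60.38	5.90	none
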