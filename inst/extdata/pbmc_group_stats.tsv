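comparison	gene	lfc	p	mean_case	sd_case	mean_ctrl	sd_ctrl
All	PPARG	-0.82	0.22	5.85	1.09	6.67	0.90
All	PPARD	-0.54	0.34	4.63	1.33	5.17	1.19
All	PPARA	0.02	0.49	6.50	0.86	6.47	1.20
Female	PPARG	-1.30	0.13	5.86	1.13	7.15	0.23
Female	PPARD	-0.55	0.02	6.31	0.26	6.85	0.97
Female	PPARA	0.28	0.39	6.57	0.97	6.29	1.40
Male	PPARG	-0.43	0.36	5.08	1.24	5.51	1.13
Male	PPARD	-0.26	0.35	8.98	0.68	9.25	1.04
Male	PPARA	-0.26	0.36	6.40	0.74	6.65	1.00
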