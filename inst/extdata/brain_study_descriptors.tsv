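study_id	n_case	n_ctrl	tissue	country
GSE12649	35	34	Prefrontal cortex	Japan
GSE12654	13	15	Prefrontal cortex	Japan
GSE12679	16	11	Dorsolateral prefrontal cortex	United Kingdom
GSE17612	28	23	BA10	United Kingdom
GSE21138	30	29	Prefrontal cortex	U.S.A.
GSE21935	23	19	BA22	United Kingdom
GSE26927	10	55	Multiple Brodmann areas	United Kingdom
GSE35974	44	50	Parietal cortex	China
GSE35977	51	50	Parietal cortex	China
GSE35978	95	100	Parietal cortex	China
GSE53987	48	55	Prefrontal cortex (BA46)	U.S.A.
GSE62191	29	30	Frontal cortex	Brazil
GSE87610	65	72	Prefrontal cortex	U.S.A.
GSE93987	67	106	Dorsolateral prefrontal cortex	U.S.A.
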