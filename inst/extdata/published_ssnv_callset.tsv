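ssnv	sample_id	diagnosis	cell_type	gnomad_af	n_reads	vaf_pct	type	gene	cadd_raw	cadd_phred
9:130263483|C>T	C1	Control	Non-Neuronal	0	313	2.88	Intronic	LRSAM1	0.18	4.52
12:120582181|G>T	C5	Control	Non-Neuronal	0	188	3.72	Exonic (loss-of-function)	GCN1	6.47	30.00
17:2575935|G>T	C5	Control	Neuronal	0	80	6.25	Intronic	PAFAH1B1	-0.11	1.68
5:133747485|C>T	C6	Control	Neuronal	1.48E-05	187	3.74	Exonic (non-synonymous)	CDKN2AIPNL	2.41	18.91
X:25014005|C>T	C6	Control	Neuronal	0	660	2.27	Exonic (loss-of-function)	POLA1	12.14	38.00
15:42439899|C>T	C10	Control	Neuronal	0	182	3.85	Exonic (non-synonymous)	PLA2G4F	6.59	31.00
9:2718448|C>T	C10	Control	Non-Neuronal	0	214	3.74	Exonic (non-synonymous)	KCNV2	5.59	26.50
15:45695252|G>A	S1	SCZ	Neuronal	0	117	4.27	Exonic (non-synonymous)	SPATA5L1	1.00	10.65
8:6338368|C>T	S1	SCZ	Non-Neuronal	7.45E-05	132	3.79	Exonic (non-synonymous)	MCPH1	6.53	31.00
1:43850087|C>T	S3	SCZ	Non-Neuronal	5.82E-05	413	3.87	UTR3	MED8	0.16	4.25
11:120838140|C>T	S3	SCZ	Non-Neuronal	0	173	3.47	Intronic	GRIK4	-0.01	2.52
4:52779777|C>T	S3	SCZ	Non-Neuronal	0	243	3.29	UTR3	DCUN1D4	0.94	10.32
X:120183145|C>G	S3	SCZ	Non-Neuronal	0	398	2.76	Exonic (non-synonymous)	GLUD2	3.92	23.50
X:75650577|C>G	S3	SCZ	Non-Neuronal	0	403	2.73	Exonic (non-synonymous)	MAGEE1	3.22	22.70
X:77298037|G>A	S3	SCZ	Non-Neuronal	0	117	4.27	Intronic	ATP7A	-0.13	1.52
9:133267386|G>A	S4	SCZ	Neuronal	0	196	4.59	Exonic (synonymous)	HMCN2	0.64	8.41
1:228540840|C>T	S7	SCZ	Non-Neuronal	0	242	3.72	Intronic	OBSCN	0.50	7.44
19:58187980|G>A	S7	SCZ	Non-Neuronal	0	183	7.10	Intronic	ZSCAN4	0.12	3.87
22:41527619|C>T	S7	SCZ	Non-Neuronal	0	146	4.79	Exonic (non-synonymous)	EP300	5.93	27.60
4:163032431|G>A	S7	SCZ	Neuronal	1.65E-05	204	4.41	Exonic (loss-of-function)	FSTL5	10.65	36.00
11:89155084|C>T	S8	SCZ	Non-Neuronal	4.99E-05	180	6.11	Exonic (synonymous)	NOX4	2.29	18.11
11:89155084|C>T	S8	SCZ	Neuronal	4.99E-05	102	4.90	Exonic (synonymous)	NOX4	2.29	18.11
12:49360144|G>A	S8	SCZ	Non-Neuronal	1.83E-04	343	4.96	Exonic (non-synonymous)	WNT10B	7.27	34.00
12:49360144|G>A	S8	SCZ	Neuronal	1.83E-04	409	2.93	Exonic (non-synonymous)	WNT10B	7.27	34.00
22:32198753|C>T	S8	SCZ	Non-Neuronal	0	263	3.04	Exonic (non-synonymous)	DEPDC5	7.10	34.00
5:177688699|G>A	S8	SCZ	Non-Neuronal	0	271	2.95	Intronic	COL23A1	0.17	4.41
16:72166900|G>A	S9	SCZ	Neuronal	0	159	3.77	Intronic	PMFBP1	1.08	11.11
16:90015951|G>A	S9	SCZ	Neuronal	0	162	3.70	Exonic (synonymous)	DEF8	0.35	6.14
17:78182086|G>A	S9	SCZ	Neuronal	7.27E-05	273	2.93	Exonic (non-synonymous)	CARD14	2.84	21.60
19:7566139|G>T	S9	SCZ	Neuronal	0	145	3.45	Exonic (non-synonymous)	C19orf45	1.00	10.66
22:42373091|G>A	S9	SCZ	Non-Neuronal	0	108	5.56	Intronic	SEPT3	1.74	14.63
8:30705911|G>T	S9	SCZ	Non-Neuronal	0	431	2.78	Exonic (non-synonymous)	TEX15	3.62	23.20
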