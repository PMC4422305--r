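amino_acid	codon	rscu_high	n_high	rscu_low	n_low	optimal_reported
Ala	GCU	0.64	288	1.66	315	FALSE
Ala	GCC	1.80	818	0.46	88	TRUE
Ala	GCA	0.29	133	1.65	313	FALSE
Ala	GCG	1.27	575	0.23	43	TRUE
Asn	AAU	0.34	130	1.39	549	FALSE
Asn	AAC	1.66	631	0.61	239	TRUE
Gln	CAA	0.44	174	1.43	370	FALSE
Gln	CAG	1.56	615	0.57	146	TRUE
Phe	UUU	0.24	91	1.48	396	FALSE
Phe	UUC	1.76	680	0.52	140	TRUE
Ser	UCU	0.71	153	1.49	233	FALSE
Ser	UCC	1.71	366	0.44	69	TRUE
Ser	UCA	0.42	90	1.77	276	FALSE
Ser	UCG	1.56	335	0.34	53	TRUE
Ser	AGU	0.34	72	1.40	219	FALSE
Ser	AGC	1.26	271	0.55	86	TRUE
Gly	GGU	0.65	240	1.49	291	FALSE
Gly	GGC	1.91	703	0.58	113	TRUE
Gly	GGA	0.75	277	1.55	303	FALSE
Gly	GGG	0.69	254	0.39	76	TRUE
Ile	AUU	0.34	99	1.37	407	FALSE
Ile	AUC	2.23	652	0.39	115	TRUE
Ile	AUA	0.43	126	1.24	368	FALSE
Thr	ACU	0.57	146	1.49	275	FALSE
Thr	ACC	1.68	433	0.43	79	TRUE
Thr	ACA	0.43	110	1.85	343	FALSE
Thr	ACG	1.32	339	0.23	43	TRUE
Leu	UUA	0.17	49	2.18	442	FALSE
Leu	UUG	0.61	179	1.30	264	FALSE
Leu	CUU	0.30	88	0.89	181	FALSE
Leu	CUC	2.05	602	0.35	71	TRUE
Leu	CUA	0.27	78	0.75	152	FALSE
Leu	CUG	2.60	764	0.53	108	TRUE
Asp	GAU	0.38	226	1.46	587	FALSE
Asp	GAC	1.62	958	0.54	217	TRUE
Glu	GAA	0.57	414	1.59	769	FALSE
Glu	GAG	1.43	1036	0.41	197	TRUE
His	CAU	0.38	97	1.44	196	FALSE
His	CAC	1.62	416	0.56	76	TRUE
Pro	CCU	0.48	122	1.46	204	FALSE
Pro	CCC	1.65	418	0.35	49	TRUE
Pro	CCA	0.36	91	1.87	261	FALSE
Pro	CCG	1.50	380	0.32	45	TRUE
Lys	AAA	0.48	278	1.55	924	FALSE
Lys	AAG	1.52	870	0.45	269	TRUE
Arg	CGU	0.63	126	0.76	81	FALSE
Arg	CGC	2.49	495	0.21	22	TRUE
Arg	CGA	0.37	74	0.87	93	FALSE
Arg	CGG	1.04	207	0.23	24	TRUE
Arg	AGA	0.61	121	3.05	325	FALSE
Arg	AGG	0.86	172	0.89	95	FALSE
Val	GUU	0.41	144	1.59	363	FALSE
Val	GUC	1.32	469	0.48	109	TRUE
Val	GUA	0.36	126	1.26	289	FALSE
Val	GUG	1.91	678	0.67	153	TRUE
Cys	UGU	0.35	64	1.50	179	FALSE
Cys	UGC	1.65	302	0.50	60	TRUE
Trp	UGG	1.00	219	1.00	157	FALSE
Tyr	UAU	0.29	100	1.40	322	FALSE
Tyr	UAC	1.71	595	0.60	138	TRUE
TER	UGA	0.94	17	0.61	11	FALSE
TER	UAA	1.50	27	1.83	33	FALSE
TER	UAG	0.56	10	0.56	10	FALSE
Met	AUG	1.00	507	1.00	359	FALSE
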