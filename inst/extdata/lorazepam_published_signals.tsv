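soc	pt	cases	ror	ror_low	ror_high	prr	prr_low	prr_high	ic	ic025	ebgm	ebgm05
psychiatric disorders	sopor	2407	13.1	12.53	13.69	13.06	12.56	13.58	3.42	3.36	10.7	10.31
nervous system disorders	neuroleptic malignant syndrome	1267	7.63	7.2	8.09	7.62	7.18	8.08	2.77	2.68	6.8	6.47
nervous system disorders	sedation	1249	3.47	3.28	3.67	3.46	3.26	3.67	1.73	1.65	3.32	3.16
injury, poisoning and procedural complications	muscle injury	435	5.01	4.54	5.52	5	4.53	5.51	2.22	2.08	4.66	4.29
psychiatric disorders	drug abuse	4135	3.29	3.19	3.4	3.28	3.15	3.41	1.66	1.61	3.15	3.07
psychiatric disorders	delirium	1896	3.84	3.67	4.03	3.84	3.69	3.99	1.87	1.8	3.65	3.51
psychiatric disorders	catatonia	745	11.47	10.59	12.41	11.46	10.6	12.39	3.27	3.15	9.62	9
gastrointestinal disorders	duodenal ulcer perforation	507	7.99	7.28	8.77	7.99	7.24	8.81	2.82	2.69	7.08	6.55
cardiac disorders	pericarditis	629	3.09	2.85	3.35	3.09	2.86	3.34	1.57	1.46	2.97	2.78
psychiatric disorders	psychotic disorder	1441	3.21	3.05	3.39	3.21	3.03	3.4	1.63	1.55	3.09	2.95
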