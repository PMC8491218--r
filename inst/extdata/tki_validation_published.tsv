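drug	model	n_sensitive	n_resistant	acc_sensitive	acc_resistant	mcc	overall
erlotinib	curated	9	34	100	3	0.08	23
erlotinib	pathway_extended	9	34	42	93	0.41	83
sorafenib	curated	21	46	96	29	0.28	50
sorafenib	pathway_extended	21	46	72	95	0.72	88
gefitinib	curated	10	2	13	100	0.16	29
gefitinib	pathway_extended	10	2	100	50	0.67	91
lapatinib	curated	8	23	13	100	0.31	77
lapatinib	pathway_extended	8	23	63	74	0.33	71
imatinib	curated	17	6	41	83	0.23	52
imatinib	pathway_extended	17	6	84	33	0.18	70
sunitinib	curated	6	12	87	45	0.31	59
sunitinib	pathway_extended	6	12	67	92	0.61	83
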