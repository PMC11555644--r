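vid	gene	chrom	pos	study	sex	or_	l95	u95	p
rs2346609	RBFOX1	16	7260432	GliomaScan	female	1.20	1.00	1.43	0.0536
rs2346609	RBFOX1	16	7260432	AGOG	female	1.17	0.94	1.46	0.1677
rs2346609	RBFOX1	16	7260432	GICC	female	1.24	1.10	1.41	0.0008
rs2346609	RBFOX1	16	7260432	UCSF_Mayo	female	1.31	1.11	1.56	0.0019
rs2346609	RBFOX1	16	7260432	GliomaScan	male	0.99	0.84	1.16	0.8613
rs2346609	RBFOX1	16	7260432	AGOG	male	0.95	0.78	1.16	0.6419
rs2346609	RBFOX1	16	7260432	GICC	male	0.99	0.88	1.10	0.7969
rs2346609	RBFOX1	16	7260432	UCSF_Mayo	male	0.99	0.86	1.14	0.9173
rs35042965	PRDM2	1	14184325	GliomaScan	female	0.99	0.79	1.23	0.9103
rs35042965	PRDM2	1	14184325	AGOG	female	1.01	0.77	1.33	0.9322
rs35042965	PRDM2	1	14184325	GICC	female	0.98	0.83	1.14	0.7734
rs35042965	PRDM2	1	14184325	UCSF_Mayo	female	0.99	0.80	1.22	0.9203
rs35042965	PRDM2	1	14184325	GliomaScan	male	0.91	0.74	1.10	0.3269
rs35042965	PRDM2	1	14184325	AGOG	male	0.75	0.58	0.97	0.0285
rs35042965	PRDM2	1	14184325	GICC	male	0.81	0.71	0.92	0.0016
rs35042965	PRDM2	1	14184325	UCSF_Mayo	male	0.77	0.65	0.92	0.0030
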