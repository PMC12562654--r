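side	rank	gene	score	log2fc	padj
left	1	PRAC1	100.00	-3.78	3.95e-39
left	2	LY6G6D	27.02	-1.39	4.71e-11
left	3	HOXB13	24.02	-0.91	1.12e-15
left	4	ELAVL2	19.07	-0.83	9.47e-14
left	5	MAP7D2	16.78	-1.24	5.64e-10
left	6	MUC12	16.56	-1.29	1.11e-8
left	7	PLAGL2	16.18	-0.61	7.36e-9
left	8	CLDN8	15.77	-0.96	3.30e-8
left	9	HOXB13	14.17	-0.90	2.13e-12
left	10	GPR15LG	13.44	-0.99	2.07e-4
left	11	AK4	12.98	-0.62	2.12e-5
left	12	CYP2B6	12.11	-0.67	2.16e-4
left	13	LOC101929880	11.63	-0.69	1.57e-6
left	14	SLC26A3	11.17	-1.46	7.06e-5
left	15	C10orf99	10.69	-0.95	4.47e-5
left	16	PCK1	10.65	-0.87	8.01e-4
left	17	PNLIPRP2	10.07	-0.74	7.97e-6
left	18	AMACR	9.94	-0.62	1.04e-5
left	19	SATB2	9.23	-0.66	7.60e-5
left	20	CKMT2	9.17	-0.87	1.28e-5
right	1	HOXC6	200.00	1.59	6.00e-21
right	2	DUSP4	25.74	0.71	1.06e-7
right	3	KLK11	20.84	0.69	1.93e-6
right	4	GPR126	20.69	0.73	4.12e-6
right	5	REG1A	20.01	1.66	1.72e-5
right	6	SBSPON	19.41	0.76	5.78e-5
right	7	CPS1	18.54	0.71	1.25e-3
right	8	REG4	17.89	1.08	8.52e-3
right	9	SBSPON	17.52	0.96	2.89e-5
right	10	TCN1	17.17	1.20	3.71e-5
right	11	L1TD1	15.87	0.95	2.09e-4
right	12	SCG5	15.77	0.69	2.62e-5
right	13	KLK10	15.27	0.87	4.91e-4
right	14	PLA2G4A	14.62	1.03	6.44e-7
right	15	CPS1	13.94	0.72	1.33e-3
right	16	HOXA10-HOXA9	13.84	0.67	2.50e-3
right	17	HOXB6	13.52	0.80	3.57e-7
right	18	DUSP4	13.30	0.68	2.54e-7
right	19	SERPINB5	13.19	0.95	3.17e-5
right	20	CLDN2	12.64	0.70	1.29e-3
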