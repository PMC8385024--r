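accession	gene	z_I	z_II	z_III	z_IV	log2fc	p
P05556	ITGB1	-0.77	1.46	-0.54	-0.15	-0.97	0.005
P21926	CD9	-0.81	1.26	-0.82	0.37	-0.70	0.016
Q86SQ4	GPR126	-0.72	1.49	-0.36	-0.41	-1.02	0.03
P20827	EFNA1	-1.06	1.27	-0.47	0.27	-1.00	0.016
Q15828	CST6	-1.02	1.36	-0.37	0.03	-0.97	0.045
P30530	AXL	-1.38	1.02	0.3	0.07	-0.89	0.039
P22455	FGFR4	-0.61	1.46	-0.7	-0.17	-0.80	0.033
P43121	MCAM	-0.6	1.48	-0.66	-0.23	-0.76	0.005
Q14118	DAG1	-0.45	1.5	-0.4	-0.66	-0.66	0.043
P98160	HSPG2	-1.03	1.3	0.22	-0.49	-0.64	0.049
P10316	HLA-A	-1.21	1.16	-0.32	0.37	-0.74	0.052
P01034	CST3	-1.37	0.92	-0.1	0.55	-0.72	0.06
P39060	COL18A1	-0.94	1.41	-0.4	-0.08	-0.74	0.064
O00592	PODXL	-1.33	1.1	-0.03	0.26	-0.62	0.09
P10909	CLU	-1.4	0.99	0.24	0.19	-0.85	0.092
Q99715	COL12A1	-1.25	1.18	0.21	-0.14	-0.60	0.122
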