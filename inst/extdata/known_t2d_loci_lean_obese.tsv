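variant_id	gene	chrom	risk_allele	or_lean	ci_low_lean	ci_high_lean	p_lean	or_obese	ci_low_obese	ci_high_obese	p_obese
rs7903146	TCF7L2	10	T	1.58	1.47	1.68	2.0e-40	1.26	1.20	1.32	4.40e-21
rs11708067	ADCY5	3	A	1.25	1.15	1.35	5.7e-08	1.07	1.01	1.14	0.01
rs10923931	NOTCH2	1	T	1.22	1.11	1.35	0.00007	1.06	0.98	1.13	0.14
rs13266634	SLC30A8	8	C	1.24	1.15	1.34	5.1e-08	1.12	1.06	1.19	0.00005
rs2237892	KCNQ1	11	C	1.29	1.12	1.48	0.0003	1.11	1.01	1.22	0.02
rs10010131	WFS1	4	G	1.14	1.07	1.22	0.00005	1.07	1.02	1.12	0.004
rs10811661	CDKNA/2B	9	T	1.22	1.12	1.33	0.000007	1.12	1.05	1.19	0.0002
rs5215	KCNJ11	11	C	1.15	1.08	1.23	0.00002	1.08	1.03	1.13	0.0007
rs4457053	ZBED3	5	G	1.14	1.05	1.24	0.002	1.06	1.00	1.12	0.04
rs340874	PROX1	1	C	1.12	1.05	1.19	0.0008	1.06	1.01	1.11	0.02
rs7957197	HNF1A	12	T	1.07	0.99	1.16	0.07	1.01	0.96	1.07	0.69
rs243021	BCL11A	2	A	1.12	1.05	1.20	0.0006	1.07	1.01	1.12	0.01
rs896854	TP53INP1	8	T	1.02	0.96	1.09	0.44	1.07	1.03	1.12	0.002
rs757210	HNF1B	17	T	1.17	1.05	1.29	0.003	1.09	1.02	1.17	0.02
rs7578597	THADA	2	T	1.20	1.08	1.33	0.0008	1.12	1.04	1.20	0.004
rs1111875	HHEX	10	C	1.18	1.10	1.25	5.3e-07	1.13	1.08	1.18	6.4e-08
rs972283	KLF14	7	G	1.13	1.06	1.20	0.0002	1.09	1.04	1.14	0.0003
rs7593730	RBMS1/ITGB6	2	C	1.12	1.03	1.22	0.005	1.07	1.00	1.14	0.03
rs7754840	CDKAL1	6	C	1.19	1.11	1.27	3.80e-07	1.14	1.09	1.20	2.0e-08
rs4607103	ADAMTS9	3	C	1.03	0.95	1.11	0.47	1.07	1.01	1.13	0.01
rs1531343	HMGA2	12	C	1.13	1.01	1.27	0.03	1.20	1.10	1.31	0.00003
rs7961581	TSPAN8,LGR5	12	C	1.17	1.08	1.26	0.00007	1.13	1.06	1.20	0.00007
rs8042680	PRC1	15	A	1.07	1.00	1.14	0.05	1.04	0.99	1.09	0.10
rs11634397	ZFAND6	15	G	1.08	1.01	1.16	0.03	1.05	1.00	1.10	0.04
rs7578326	IRS1	2	A	1.10	1.03	1.18	0.008	1.07	1.02	1.13	0.006
rs1552224	CENTD2	11	A	1.05	0.96	1.14	0.27	1.08	1.02	1.15	0.01
rs1801282	PPARg	3	C	1.14	1.04	1.26	0.008	1.11	1.04	1.18	0.003
rs12779790	CAMK1D	10	G	1.12	1.03	1.22	0.009	1.09	1.02	1.16	0.008
rs864745	JAZF1	7	T	1.09	1.03	1.16	0.006	1.08	1.03	1.12	0.001
rs780094	GCKR	2	C	1.04	0.98	1.11	0.19	1.03	0.98	1.08	0.22
rs13292136	TLE4	9	C	1.15	1.00	1.31	0.04	1.12	1.00	1.24	0.04
rs231362	KCNQ1	11	G	1.09	1.02	1.17	0.01	1.08	1.03	1.14	0.003
rs4607517	GCK	7	A	1.03	0.94	1.12	0.55	1.04	0.98	1.10	0.20
rs1470579	IGF2BP2	3	C	1.15	1.07	1.23	0.00009	1.16	1.10	1.23	6.4e-08
rs10830963	MTNR1B	11	G	1.11	1.03	1.20	0.007	1.10	1.04	1.16	0.0005
rs2191349	DGKB/TME195	7	T	1.03	0.97	1.10	0.38	1.04	0.99	1.08	0.13
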