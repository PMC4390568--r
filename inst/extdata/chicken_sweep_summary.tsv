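chrom	chrom_size_mb	n_sweeps	mean_kb	min_kb	max_kb	coverage_pct	snps_mean	snps_min	snps_max	genes_mean	genes_min	genes_max	genes_total
1	200.99	36	127.28	1.74	789.46	2.22	1348.37	18	10096	1.69	0	8	61
2	154.87	25	89.55	0.08	505.77	1.45	787.00	5	5238	1.64	0	13	41
3	113.66	17	93.20	0.22	535.04	1.23	943.65	9	5336	1.47	0	6	25
4	94.23	21	124.44	0.75	754.56	2.91	1324.00	16	7583	2.71	0	32	57
5	62.24	1	1.29	1.29	1.29	0.002	16.00	16	16	1.00	1	1	1
6	37.40	5	41.12	17.31	74.93	0.55	409.00	201	961	2.00	0	5	10
7	38.38	3	272.65	206.99	393.85	2.13	2724.70	2530	3019	2.67	2	4	8
8	30.67	1	103.19	103.19	103.19	0.34	570.00	570	570	2.00	2	2	2
10	22.56	6	11.04	0.10	46.48	0.29	142.00	7	555	2.17	1	6	13
11	21.93	5	303.97	10.10	1018.14	6.93	1623.60	86	4532	3.00	0	5	15
12	20.54	1	15.86	15.86	15.86	0.08	94.00	94	94	0.00	0	0	0
13	18.91	1	0.01	0.01	0.01	0.00	2.00	2	2	1.00	1	1	1
14	15.82	4	112.17	22.41	166.90	2.84	762.75	186	1620	5.00	4	6	20
17	11.18	1	107.06	107.06	107.06	0.96	650.00	650	650	1.00	1	1	1
20	13.99	1	151.00	151.00	151.00	1.08	1895.00	1895	1895	6.00	6	6	6
24	6.40	1	6.81	6.81	6.81	0.11	114.00	114	114	1.00	1	1	1
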