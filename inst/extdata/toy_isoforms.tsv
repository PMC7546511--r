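gene_id	transcript_id	N1	N2	N3	N4	T1	T2	T3	T4
g1	g1_tx1	7.208	8.529	7	8.554	29.421	17.552	22.773	20.301
g1	g1_tx2	16.263	12.088	12.742	8.397	3.786	4.65	6.508	2.297
g1	g1_tx3	2.063	1.604	1.257	1.371	1.9	2.501	1.713	1.813
g2	g2_tx1	13.514	10.798	10.665	9.522	28.602	37.532	18.64	38.244
g2	g2_tx2	1.957	2.519	2.283	2.559	7.363	4.335	6.054	7.985
g3	g3_tx1	2.063	1.662	1.848	2.471	1.694	1.466	3.18	3.525
g3	g3_tx2	11.158	7.701	14.353	20.007	7.46	8.241	6.604	14.055
g3	g3_tx3	3.079	3.73	3.34	3.653	6.152	2.837	2.801	6.509
g3	g3_tx4	1.558	3.225	3.1	2.833	2.732	2.749	4.056	7.028
g4	g4_tx1	24.527	12.764	7.439	19.282	19.795	21.179	15.1	26.049
g4	g4_tx2	2.181	3.061	4.081	2.164	2.763	1.892	2.11	0.955
g5	g5_tx1	3.581	3.935	4.055	6.113	4.009	5.48	5.602	3.101
g5	g5_tx2	3.265	7.852	1.544	4.704	3.32	2.517	6.815	6.143
g5	g5_tx3	15.841	7.157	11.501	9.687	10.746	9.423	9.946	5.771
g6	g6_tx1	5.857	2.029	1.542	4.484	3.862	5.866	2.97	5.197
g6	g6_tx2	10.091	10.513	16.731	10.336	22.028	9.851	13.058	17.36
g6	g6_tx3	0.015	0.456	0.037	0.095	0.186	0.063	0.079	0.236
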