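sample_id	total_bp	n_reads	gc_pct	avg_read_bp	n_orfs	avg_orf_aa	depth_zone
3_S	21533646	63994	37	336	65656	99	SRF
4_S	52953075	140754	38	376	149018	108	SRF
6_S	36129806	95255	48	379	98996	111	SRF
7_S	98750180	332049	38	297	335408	90	SRF
7_D	279389388	1117888	37	250	1013853	81	DCM
23_S	67695268	196190	39	345	201447	101	SRF
23_D	83539478	239447	38	349	246948	102	DCM
30_S	89180466	256028	37	348	268616	101	SRF
31_S	245463121	614743	39	399	660949	114	SRF
36_S	245945064	737506	39	333	757448	100	SRF
38_S	214253370	601110	39	356	631351	103	SRF
38_Z	223188575	638843	45	349	659041	104	OMZ
39_S	233273851	590664	43	395	629501	114	SRF
39_Z	249558778	679589	46	367	708056	108	OMZ
43_S	167515516	529506	37	316	545641	93	SRF
46_S	251310870	648425	41	388	689641	112	SRF
49_S	222417021	680573	43	327	696974	98	SRF
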