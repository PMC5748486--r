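id	chrom	pos	ref	alt	gene	context	coding_class	germline_ref	germline_alt	s1_ref	s1_alt	s2_ref	s2_alt	s3_ref	s3_alt	s4_ref	s4_alt	s5_ref	s5_alt	s6_ref	s6_alt
m01	chr1	1001	C	T	APC	ACG	missense	30	0	40	40	40	40	40	40	40	40	40	40	40	40
m02	chr1	1002	C	T	KRAS	GCG	silent	30	0	45	35	45	35	45	35	45	35	45	35	80	0
m03	chr1	1003	G	A	TP53	CGT	nonsense	30	0	78	2	80	0	80	0	80	0	80	0	80	0
m04	chr1	1004	A	T	GENE04	AAA	missense	30	0	79	1	60	20	60	20	80	0	80	0	80	0
m05	chr1	1005	C	A	GENE05	ACA	silent	28	2	50	30	50	30	50	30	50	30	50	30	50	30
m06	chr1	1006	T	C	GENE06	ATG	missense	29	1	68	12	71	9	80	0	80	0	80	0	80	0
m07	chr1	1007	C	T	GENE07	TCG	missense	30	0	55	25	62	18	80	0	9	0	80	0	80	0
m08	chr1	1008	C	G	GENE08	CCT	silent	30	0	55	25	10	0	80	0	80	0	80	0	80	0
m09	chr1	1009	T	A	GENE09	CTA	nonsense	30	0	50	30	50	30	50	30	50	30	50	30	3	0
m10	chr1	1010	C	T	GENE10	ACT	missense	30	0	80	0	80	0	80	0	80	0	80	0	80	0
m11	chr1	1011	G	C	GENE11	TGA	missense	30	0	80	0	80	0	80	0	80	0	80	0	65	15
m12	chr1	1012	C	T	GENE12	CCG	missense	30	0	60	20	60	20	60	20	60	20	80	0	80	0
m13	chr1	1013	T	G	GENE13	ATA	silent	30	0	75	5	75	5	80	0	80	0	80	0	79	1
m14	chr1	1014	C	T	GENE14	GCG	missense	30	0	80	0	80	0	72	8	80	0	0	0	80	0
m15	chr1	1015	A	G	GENE15	CAT	missense	25	5	58	22	58	22	58	22	58	22	58	22	58	22
m16	chr1	1016	C	T	GENE16	ACG	silent	30	0	50	30	79	1	50	30	50	30	50	30	50	30
m17	chr1	1017	T	C	GENE17	TTG	missense	30	0	80	0	80	0	80	0	62	18	62	18	62	18
m18	chr1	1018	C	A	GENE18	GCC	nonsense	30	0	77	3	78	2	80	0	80	0	80	0	80	0
m19	chr1	1019	G	T	GENE19	AGA	missense	30	0	80	0	20	60	80	0	80	0	80	0	80	0
m20	chr1	1020	T	C	GENE20	GTT	silent	30	0	70	10	70	10	70	10	70	10	70	10	70	10
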