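gene_id	subj_001_v01	subj_001_v02	subj_001_v03	subj_001_v04	subj_002_v01	subj_002_v02	subj_002_v03	subj_002_v04	subj_003_v01	subj_003_v02	subj_003_v03	subj_003_v04	subj_004_v01	subj_004_v02	subj_004_v03	subj_004_v04
sp_0001_g001	487	0	809	0	0	497	0	423	862	0	770	0	966	0	902	756
sp_0001_g002	487	0	738	0	0	526	0	421	871	0	764	0	970	0	968	805
sp_0001_g003	458	0	780	0	0	519	0	396	928	0	728	0	981	0	971	813
sp_0001_g004	469	0	739	0	0	472	0	384	917	0	708	0	961	0	960	762
sp_0001_g005	521	0	748	0	0	519	0	395	918	0	778	0	950	0	942	821
sp_0002_g001	0	0	0	0	0	0	0	0	65	0	0	0	0	0	0	0
sp_0002_g002	0	0	0	0	0	0	0	0	53	0	0	0	0	0	0	0
sp_0002_g003	0	0	0	0	0	0	0	0	54	0	0	0	0	0	0	0
sp_0002_g004	0	0	0	0	0	0	0	0	67	0	0	0	0	0	0	0
sp_0002_g005	0	0	0	0	0	0	0	0	71	0	0	0	0	0	0	0
sp_0003_g001	229	0	0	0	0	434	0	0	0	912	233	778	0	377	43	0
sp_0003_g002	193	0	0	0	0	478	0	0	0	991	238	828	0	314	35	0
sp_0003_g003	228	0	0	0	0	435	0	0	0	902	227	812	0	346	40	0
sp_0003_g004	190	0	0	0	0	451	0	0	0	991	218	743	0	325	40	0
sp_0003_g005	180	0	0	0	0	447	0	0	0	904	225	798	0	318	48	0
sp_0004_g001	63	2	0	51	79	0	31	119	2	21	1	0	5	134	0	107
sp_0004_g002	47	5	0	59	61	0	19	109	3	19	0	0	5	107	0	94
sp_0004_g003	43	1	0	58	74	0	22	115	0	21	0	0	2	116	0	123
sp_0004_g004	58	7	0	64	79	0	21	111	2	24	2	0	2	139	0	131
sp_0004_g005	53	3	0	64	77	0	25	116	5	18	3	0	4	132	0	119
sp_0005_g001	0	37	144	210	0	0	278	0	31	31	8	118	3	458	11	0
sp_0005_g002	0	28	139	201	0	0	265	0	24	51	14	142	3	448	3	0
sp_0005_g003	0	53	137	198	0	0	227	0	26	36	16	145	3	445	11	0
sp_0005_g004	0	50	127	213	0	0	282	0	33	38	14	154	2	490	9	0
sp_0005_g005	0	46	121	212	0	0	245	0	22	41	12	148	0	512	12	0
sp_0006_g001	56	11	0	45	342	14	313	102	6	0	6	35	27	66	1	93
sp_0006_g002	61	12	0	46	356	16	323	104	13	0	9	41	35	47	1	98
sp_0006_g003	60	7	0	52	371	16	306	98	5	0	7	30	32	58	0	90
sp_0006_g004	50	9	0	50	402	17	349	112	14	0	10	36	30	54	1	82
sp_0006_g005	54	14	0	51	347	18	329	106	8	0	9	51	19	69	2	106
sp_0007_g001	219	949	106	521	569	0	404	272	0	0	0	0	0	0	0	0
sp_0007_g002	217	908	107	524	551	0	389	252	0	0	0	0	0	0	0	0
sp_0007_g003	184	961	103	545	575	0	395	270	0	0	0	0	0	0	0	0
sp_0007_g004	204	991	96	540	573	0	385	258	0	0	0	0	0	0	0	0
sp_0007_g005	189	906	106	519	544	0	392	252	0	0	0	0	0	0	0	0
sp_0008_g001	0	0	0	178	0	28	0	113	0	0	0	27	0	11	0	0
sp_0008_g002	0	0	0	140	0	35	0	115	0	0	0	26	0	7	0	0
sp_0008_g003	0	0	0	153	0	32	0	131	0	0	0	31	0	6	0	0
sp_0008_g004	0	0	0	152	0	25	0	108	0	0	0	32	0	11	0	0
sp_0008_g005	0	0	0	154	0	21	0	118	0	0	0	25	0	10	0	0
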