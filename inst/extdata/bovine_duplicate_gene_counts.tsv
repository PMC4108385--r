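chromosome	n_genes	n_dup_intra	n_dup_inter	n_ss_intra	n_ss_inter
1	985	52	175	14	24
2	1021	34	201	16	18
3	1372	124	258	66	23
4	855	78	146	42	14
5	1323	122	256	78	28
6	692	28	128	8	8
7	1396	144	252	64	16
8	829	48	135	28	6
9	602	28	107	10	18
10	1074	114	189	72	19
11	1047	54	205	12	13
12	414	12	90	4	6
13	850	40	178	22	18
14	571	14	115	4	16
15	1050	220	139	144	27
16	710	36	129	12	15
17	665	44	119	14	17
18	1236	138	167	60	12
19	1347	102	230	40	15
20	384	14	69	2	8
21	731	22	118	18	13
22	608	14	127	2	11
23	785	100	94	56	13
24	347	18	59	6	4
25	766	50	116	14	5
26	437	26	81	6	13
27	274	16	56	10	6
28	355	10	61	6	5
29	705	94	111	64	14
X	1128	156	199	100	25
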