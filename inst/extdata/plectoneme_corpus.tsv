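id	seed	n	size_bp	chirality	tip_bp
1	173128	600	280	-1	302
2	624657	600	98	-1	185
3	435586	600	61	1	479
4	312402	600	278	-1	281
5	637075	600	138	-1	277
6	859555	600	185	-1	432
7	174146	600	202	1	437
8	401781	600	262	1	218
9	827859	600	162	-1	260
10	76858	600	230	-1	157
11	990605	600	156	-1	247
12	522194	600	77	-1	215
13	134599	600	176	-1	332
14	15173	600	153	-1	239
15	359607	600	182	1	219
16	346058	600	154	-1	426
17	990213	600	275	-1	193
18	83887	600	288	-1	194
19	927442	600	112	1	134
20	942495	600	278	-1	228
21	689084	600	153	1	345
22	361506	600	143	1	305
23	811659	600	293	-1	196
24	950802	600	282	1	314
25	183876	600	146	-1	285
26	421389	600	191	1	163
27	261179	600	273	-1	321
28	48946	600	130	-1	199
29	620355	600	153	1	184
30	858604	600	141	-1	400
31	134969	600	97	-1	280
32	473780	600	236	1	325
33	847414	600	94	1	195
34	39795	600	112	-1	497
35	625719	600	183	1	316
36	90086	600	268	1	315
37	486259	600	137	1	157
38	413849	600	247	-1	269
39	43299	600	126	-1	489
40	448134	600	235	-1	335
41	10029	600	113	1	198
42	40302	600	112	-1	343
43	514052	600	196	-1	158
44	249965	600	243	-1	223
45	93623	600	276	1	188
46	350518	600	228	-1	250
47	308933	600	267	-1	374
48	401356	600	173	1	435
49	640461	600	215	1	228
50	216855	600	103	-1	190
51	60592	600	244	-1	325
52	643375	600	126	1	146
53	175881	600	245	-1	369
54	125418	600	149	-1	207
55	840049	600	257	-1	327
56	120861	600	178	-1	364
57	563703	600	200	-1	196
58	652315	600	228	-1	407
59	738695	600	191	1	250
60	798870	600	81	1	483
61	735040	600	161	1	475
62	969828	600	225	-1	377
63	759065	600	218	-1	405
64	349779	600	129	1	153
65	731481	600	95	1	414
66	647024	600	74	-1	506
67	361313	600	160	-1	476
68	187628	600	265	-1	374
69	188554	600	205	-1	447
70	511103	600	220	1	385
71	459636	600	90	1	340
72	737847	600	251	1	277
73	701730	600	278	1	248
74	583735	600	107	-1	219
75	165061	600	299	-1	366
76	973976	600	134	-1	264
77	79978	600	184	-1	342
78	518258	600	93	1	384
79	999530	600	216	-1	311
80	995645	600	243	-1	421
81	114846	600	209	-1	372
82	151520	600	155	-1	157
83	414582	600	140	-1	402
84	937360	600	223	1	389
85	675532	600	187	1	383
86	522949	600	162	1	436
87	827713	600	193	1	337
88	256697	600	159	1	316
89	537301	600	228	-1	203
90	368266	600	182	-1	138
91	521124	600	145	-1	476
92	108544	600	116	-1	190
93	921180	600	287	-1	259
94	675392	600	85	-1	85
95	396499	600	69	-1	218
96	696137	600	103	1	386
97	282152	600	210	-1	278
98	435581	600	195	-1	247
99	369334	600	244	1	351
100	523579	600	192	1	260
101	330583	600	143	-1	315
102	75596	600	272	-1	413
103	564285	600	131	-1	389
104	418057	600	297	1	302
105	578710	600	184	1	433
106	672011	600	223	1	240
107	973855	600	247	1	179
108	684602	600	174	-1	140
109	594396	600	120	-1	478
110	694190	600	271	-1	176
111	865597	600	282	1	353
112	387936	600	167	-1	227
113	555827	600	291	1	392
114	886043	600	198	-1	435
115	215059	600	66	1	102
116	922732	600	105	-1	349
117	571803	600	206	1	268
118	367930	600	79	-1	175
119	167952	600	292	1	413
120	729872	600	274	-1	350
121	253833	600	253	1	361
122	120378	600	169	-1	433
123	812502	600	142	-1	127
124	907572	600	201	-1	378
125	967725	600	174	1	342
126	854269	600	139	-1	413
127	370482	600	233	1	408
128	4935	600	96	-1	331
129	315334	600	300	-1	395
130	378086	600	244	1	348
131	866961	600	285	-1	324
132	177457	600	181	1	345
133	143530	600	98	1	357
134	535320	600	260	-1	329
135	892950	600	269	-1	356
136	194710	600	157	1	149
137	61659	600	189	1	425
138	747235	600	242	-1	390
139	593357	600	147	1	418
140	200586	600	290	1	271
141	563878	600	216	1	385
142	814804	600	174	-1	168
143	354704	600	165	1	293
144	774853	600	249	1	271
145	343475	600	276	-1	402
146	824533	600	153	-1	332
147	434396	600	185	1	189
148	786865	600	203	1	330
149	877882	600	106	-1	211
150	73360	600	284	1	388
151	994048	600	161	1	174
152	556800	600	193	-1	430
153	768125	600	191	-1	464
154	435518	600	151	-1	136
155	9038	600	256	-1	217
156	885356	600	128	-1	296
157	185881	600	173	-1	273
158	388484	600	195	1	437
159	658986	600	124	-1	308
160	326563	600	91	1	388
161	337393	600	213	1	395
162	440546	600	70	-1	127
163	148710	600	272	1	194
164	439957	600	169	1	181
165	984184	600	185	-1	335
166	100661	600	214	-1	359
167	28162	600	139	1	165
168	688732	600	62	-1	429
169	42091	600	236	1	380
170	624658	600	82	-1	108
171	861922	600	230	1	272
172	143481	600	105	-1	296
173	594558	600	143	-1	212
174	20273	600	295	1	220
175	176162	600	85	1	330
176	934183	600	192	-1	435
177	792728	600	61	1	465
178	782882	600	173	1	204
179	371505	600	181	-1	175
180	57056	600	165	1	324
181	701222	600	203	1	282
182	649201	600	278	-1	261
183	302740	600	163	-1	288
184	767510	600	66	1	160
185	209104	600	73	1	344
186	629376	600	187	-1	341
187	393190	600	136	1	188
188	230907	600	161	-1	359
189	16177	600	113	-1	397
190	504759	600	86	-1	169
191	600298	600	89	1	307
192	626031	600	259	-1	356
193	559468	600	240	1	195
194	264606	600	193	-1	402
195	747940	600	186	-1	375
196	662436	600	220	-1	318
197	341446	600	182	-1	318
198	197711	600	189	1	449
199	384823	600	272	1	263
200	401570	600	300	1	221
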