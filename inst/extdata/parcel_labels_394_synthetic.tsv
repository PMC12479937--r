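node	network	division
0	DMN	cortical
1	DMN	cortical
2	DMN	cortical
3	DMN	cortical
4	DMN	cortical
5	DMN	cortical
6	DMN	cortical
7	DMN	cortical
8	DMN	cortical
9	DMN	cortical
10	DMN	cortical
11	DMN	cortical
12	DMN	cortical
13	DMN	cortical
14	DMN	cortical
15	DMN	cortical
16	DMN	cortical
17	DMN	cortical
18	DMN	cortical
19	DMN	cortical
20	DMN	cortical
21	DMN	cortical
22	DMN	cortical
23	DMN	cortical
24	DMN	cortical
25	DMN	cortical
26	DMN	cortical
27	DMN	cortical
28	DMN	cortical
29	DMN	cortical
30	DMN	cortical
31	DMN	cortical
32	DMN	cortical
33	DMN	cortical
34	DMN	cortical
35	DMN	cortical
36	DMN	cortical
37	DMN	cortical
38	DMN	cortical
39	DMN	cortical
40	DMN	cortical
41	VIS	cortical
42	VIS	cortical
43	VIS	cortical
44	VIS	cortical
45	VIS	cortical
46	VIS	cortical
47	VIS	cortical
48	VIS	cortical
49	VIS	cortical
50	VIS	cortical
51	VIS	cortical
52	VIS	cortical
53	VIS	cortical
54	VIS	cortical
55	VIS	cortical
56	VIS	cortical
57	VIS	cortical
58	VIS	cortical
59	VIS	cortical
60	VIS	cortical
61	VIS	cortical
62	VIS	cortical
63	VIS	cortical
64	VIS	cortical
65	VIS	cortical
66	VIS	cortical
67	VIS	cortical
68	VIS	cortical
69	VIS	cortical
70	VIS	cortical
71	VIS	cortical
72	VIS	cortical
73	VIS	cortical
74	VIS	cortical
75	VIS	cortical
76	VIS	cortical
77	VIS	cortical
78	VIS	cortical
79	VIS	cortical
80	FPN	cortical
81	FPN	cortical
82	FPN	cortical
83	FPN	cortical
84	FPN	cortical
85	FPN	cortical
86	FPN	cortical
87	FPN	cortical
88	FPN	cortical
89	FPN	cortical
90	FPN	cortical
91	FPN	cortical
92	FPN	cortical
93	FPN	cortical
94	FPN	cortical
95	FPN	cortical
96	FPN	cortical
97	FPN	cortical
98	FPN	cortical
99	FPN	cortical
100	FPN	cortical
101	FPN	cortical
102	FPN	cortical
103	FPN	cortical
104	DAN	cortical
105	DAN	cortical
106	DAN	cortical
107	DAN	cortical
108	DAN	cortical
109	DAN	cortical
110	DAN	cortical
111	DAN	cortical
112	DAN	cortical
113	DAN	cortical
114	DAN	cortical
115	DAN	cortical
116	DAN	cortical
117	DAN	cortical
118	DAN	cortical
119	DAN	cortical
120	DAN	cortical
121	DAN	cortical
122	DAN	cortical
123	DAN	cortical
124	DAN	cortical
125	DAN	cortical
126	DAN	cortical
127	DAN	cortical
128	DAN	cortical
129	DAN	cortical
130	DAN	cortical
131	DAN	cortical
132	DAN	cortical
133	DAN	cortical
134	DAN	cortical
135	DAN	cortical
136	VAN	cortical
137	VAN	cortical
138	VAN	cortical
139	VAN	cortical
140	VAN	cortical
141	VAN	cortical
142	VAN	cortical
143	VAN	cortical
144	VAN	cortical
145	VAN	cortical
146	VAN	cortical
147	VAN	cortical
148	VAN	cortical
149	VAN	cortical
150	VAN	cortical
151	VAN	cortical
152	VAN	cortical
153	VAN	cortical
154	VAN	cortical
155	VAN	cortical
156	VAN	cortical
157	VAN	cortical
158	VAN	cortical
159	SAL	cortical
160	SAL	cortical
161	SAL	cortical
162	SAL	cortical
163	CON	cortical
164	CON	cortical
165	CON	cortical
166	CON	cortical
167	CON	cortical
168	CON	cortical
169	CON	cortical
170	CON	cortical
171	CON	cortical
172	CON	cortical
173	CON	cortical
174	CON	cortical
175	CON	cortical
176	CON	cortical
177	CON	cortical
178	CON	cortical
179	CON	cortical
180	CON	cortical
181	CON	cortical
182	CON	cortical
183	CON	cortical
184	CON	cortical
185	CON	cortical
186	CON	cortical
187	CON	cortical
188	CON	cortical
189	CON	cortical
190	CON	cortical
191	CON	cortical
192	CON	cortical
193	CON	cortical
194	CON	cortical
195	CON	cortical
196	CON	cortical
197	CON	cortical
198	CON	cortical
199	CON	cortical
200	CON	cortical
201	CON	cortical
202	CON	cortical
203	SMH	cortical
204	SMH	cortical
205	SMH	cortical
206	SMH	cortical
207	SMH	cortical
208	SMH	cortical
209	SMH	cortical
210	SMH	cortical
211	SMH	cortical
212	SMH	cortical
213	SMH	cortical
214	SMH	cortical
215	SMH	cortical
216	SMH	cortical
217	SMH	cortical
218	SMH	cortical
219	SMH	cortical
220	SMH	cortical
221	SMH	cortical
222	SMH	cortical
223	SMH	cortical
224	SMH	cortical
225	SMH	cortical
226	SMH	cortical
227	SMH	cortical
228	SMH	cortical
229	SMH	cortical
230	SMH	cortical
231	SMH	cortical
232	SMH	cortical
233	SMH	cortical
234	SMH	cortical
235	SMH	cortical
236	SMH	cortical
237	SMH	cortical
238	SMH	cortical
239	SMH	cortical
240	SMH	cortical
241	SMM	cortical
242	SMM	cortical
243	SMM	cortical
244	SMM	cortical
245	SMM	cortical
246	SMM	cortical
247	SMM	cortical
248	SMM	cortical
249	AUD	cortical
250	AUD	cortical
251	AUD	cortical
252	AUD	cortical
253	AUD	cortical
254	AUD	cortical
255	AUD	cortical
256	AUD	cortical
257	AUD	cortical
258	AUD	cortical
259	AUD	cortical
260	AUD	cortical
261	AUD	cortical
262	AUD	cortical
263	AUD	cortical
264	AUD	cortical
265	AUD	cortical
266	AUD	cortical
267	AUD	cortical
268	AUD	cortical
269	AUD	cortical
270	AUD	cortical
271	AUD	cortical
272	AUD	cortical
273	MEM	cortical
274	MEM	cortical
275	MEM	cortical
276	MEM	cortical
277	MEM	cortical
278	CTXT	cortical
279	CTXT	cortical
280	CTXT	cortical
281	CTXT	cortical
282	CTXT	cortical
283	CTXT	cortical
284	CTXT	cortical
285	CTXT	cortical
286	ORBF	cortical
287	ORBF	cortical
288	ORBF	cortical
289	ORBF	cortical
290	ORBF	cortical
291	ORBF	cortical
292	ORBF	cortical
293	ORBF	cortical
294	ORBF	cortical
295	ORBF	cortical
296	ORBF	cortical
297	ORBF	cortical
298	ORBF	cortical
299	ORBF	cortical
300	ORBF	cortical
301	ORBF	cortical
302	ORBF	cortical
303	ORBF	cortical
304	ORBF	cortical
305	ORBF	cortical
306	ORBF	cortical
307	ORBF	cortical
308	ORBF	cortical
309	ORBF	cortical
310	ORBF	cortical
311	ORBF	cortical
312	ORBF	cortical
313	ORBF	cortical
314	ORBF	cortical
315	ORBF	cortical
316	ORBF	cortical
317	ORBF	cortical
318	ORBF	cortical
319	ORBF	cortical
320	ORBF	cortical
321	ORBF	cortical
322	ORBF	cortical
323	ORBF	cortical
324	ORBF	cortical
325	ORBF	cortical
326	ORBF	cortical
327	ORBF	cortical
328	ORBF	cortical
329	ORBF	cortical
330	ORBF	cortical
331	ORBF	cortical
332	ORBF	cortical
333	SUBCORT	subcortical
334	SUBCORT	subcortical
335	SUBCORT	subcortical
336	SUBCORT	subcortical
337	SUBCORT	subcortical
338	SUBCORT	subcortical
339	SUBCORT	subcortical
340	SUBCORT	subcortical
341	SUBCORT	subcortical
342	SUBCORT	subcortical
343	SUBCORT	subcortical
344	SUBCORT	subcortical
345	SUBCORT	subcortical
346	SUBCORT	subcortical
347	SUBCORT	subcortical
348	SUBCORT	subcortical
349	SUBCORT	subcortical
350	SUBCORT	subcortical
351	SUBCORT	subcortical
352	SUBCORT	subcortical
353	SUBCORT	subcortical
354	SUBCORT	subcortical
355	SUBCORT	subcortical
356	SUBCORT	subcortical
357	SUBCORT	subcortical
358	SUBCORT	subcortical
359	SUBCORT	subcortical
360	SUBCORT	subcortical
361	SUBCORT	subcortical
362	SUBCORT	subcortical
363	SUBCORT	subcortical
364	SUBCORT	subcortical
365	SUBCORT	subcortical
366	SUBCORT	subcortical
367	SUBCORT	subcortical
368	SUBCORT	subcortical
369	SUBCORT	subcortical
370	SUBCORT	subcortical
371	SUBCORT	subcortical
372	SUBCORT	subcortical
373	SUBCORT	subcortical
374	SUBCORT	subcortical
375	SUBCORT	subcortical
376	SUBCORT	subcortical
377	SUBCORT	subcortical
378	SUBCORT	subcortical
379	SUBCORT	subcortical
380	SUBCORT	subcortical
381	SUBCORT	subcortical
382	SUBCORT	subcortical
383	SUBCORT	subcortical
384	SUBCORT	subcortical
385	SUBCORT	subcortical
386	SUBCORT	subcortical
387	SUBCORT	subcortical
388	SUBCORT	subcortical
389	SUBCORT	subcortical
390	SUBCORT	subcortical
391	SUBCORT	subcortical
392	SUBCORT	subcortical
393	SUBCORT	subcortical
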