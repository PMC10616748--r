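gene	expressed_in_placenta
G0001	1
G0002	0
G0003	0
G0004	0
G0005	1
G0006	0
G0007	1
G0008	1
G0009	0
G0010	1
G0011	1
G0012	1
G0013	1
G0014	0
G0015	0
G0016	0
G0017	1
G0018	0
G0019	0
G0020	0
G0021	1
G0022	0
G0023	0
G0024	0
G0025	0
G0026	0
G0027	0
G0028	0
G0029	0
G0030	0
G0031	0
G0032	1
G0033	0
G0034	0
G0035	0
G0036	0
G0037	0
G0038	0
G0039	1
G0040	0
G0041	1
G0042	0
G0043	0
G0044	0
G0045	0
G0046	0
G0047	0
G0048	1
G0049	0
G0050	0
G0051	0
G0052	1
G0053	0
G0054	0
G0055	1
G0056	1
G0057	0
G0058	0
G0059	0
G0060	0
G0061	0
G0062	0
G0063	0
G0064	0
G0065	1
G0066	0
G0067	1
G0068	1
G0069	1
G0070	1
G0071	0
G0072	0
G0073	0
G0074	0
G0075	0
G0076	1
G0077	0
G0078	0
G0079	0
G0080	1
G0081	1
G0082	0
G0083	0
G0084	0
G0085	1
G0086	1
G0087	0
G0088	0
G0089	0
G0090	0
G0091	1
G0092	0
G0093	1
G0094	0
G0095	0
G0096	1
G0097	0
G0098	0
G0099	0
G0100	0
G0101	0
G0102	0
G0103	1
G0104	1
G0105	0
G0106	0
G0107	0
G0108	1
G0109	0
G0110	1
G0111	0
G0112	1
G0113	1
G0114	0
G0115	0
G0116	0
G0117	1
G0118	0
G0119	0
G0120	1
G0121	1
G0122	0
G0123	1
G0124	1
G0125	0
G0126	1
G0127	0
G0128	1
G0129	0
G0130	0
G0131	0
G0132	0
G0133	1
G0134	0
G0135	0
G0136	0
G0137	0
G0138	0
G0139	0
G0140	0
G0141	0
G0142	0
G0143	0
G0144	1
G0145	1
G0146	0
G0147	1
G0148	0
G0149	1
G0150	0
G0151	0
G0152	0
G0153	1
G0154	0
G0155	1
G0156	0
G0157	0
G0158	0
G0159	0
G0160	0
G0161	1
G0162	1
G0163	0
G0164	0
G0165	0
G0166	1
G0167	0
G0168	1
G0169	1
G0170	0
G0171	1
G0172	1
G0173	0
G0174	1
G0175	0
G0176	1
G0177	0
G0178	0
G0179	1
G0180	0
G0181	0
G0182	0
G0183	0
G0184	0
G0185	1
G0186	0
G0187	0
G0188	0
G0189	0
G0190	0
G0191	0
G0192	1
G0193	0
G0194	1
G0195	0
G0196	0
G0197	0
G0198	0
G0199	0
G0200	1
G0201	0
G0202	0
G0203	1
G0204	0
G0205	1
G0206	0
G0207	1
G0208	0
G0209	1
G0210	1
G0211	1
G0212	1
G0213	1
G0214	1
G0215	0
G0216	0
G0217	0
G0218	1
G0219	1
G0220	1
G0221	0
G0222	0
G0223	0
G0224	0
G0225	1
G0226	0
G0227	0
G0228	0
G0229	1
G0230	1
G0231	1
G0232	0
G0233	0
G0234	0
G0235	0
G0236	1
G0237	0
G0238	0
G0239	0
G0240	1
G0241	1
G0242	0
G0243	0
G0244	1
G0245	0
G0246	0
G0247	0
G0248	1
G0249	0
G0250	0
G0251	0
G0252	0
G0253	1
G0254	1
G0255	0
G0256	0
G0257	0
G0258	0
G0259	0
G0260	0
G0261	1
G0262	1
G0263	0
G0264	0
G0265	0
G0266	1
G0267	1
G0268	0
G0269	0
G0270	0
G0271	0
G0272	0
G0273	0
G0274	0
G0275	0
G0276	0
G0277	0
G0278	0
G0279	1
G0280	0
G0281	0
G0282	1
G0283	0
G0284	0
G0285	0
G0286	1
G0287	0
G0288	0
G0289	1
G0290	0
G0291	0
G0292	0
G0293	0
G0294	0
G0295	0
G0296	0
G0297	0
G0298	1
G0299	0
G0300	0
G0301	0
G0302	0
G0303	1
G0304	0
G0305	0
G0306	0
G0307	1
G0308	0
G0309	1
G0310	0
G0311	0
G0312	0
G0313	0
G0314	0
G0315	0
G0316	0
G0317	1
G0318	1
G0319	1
G0320	0
G0321	0
G0322	0
G0323	1
G0324	1
G0325	1
G0326	1
G0327	0
G0328	0
G0329	0
G0330	0
G0331	0
G0332	0
G0333	1
G0334	1
G0335	0
G0336	1
G0337	0
G0338	1
G0339	1
G0340	0
G0341	0
G0342	1
G0343	0
G0344	1
G0345	0
G0346	0
G0347	1
G0348	1
G0349	0
G0350	1
G0351	0
G0352	1
G0353	0
G0354	1
G0355	1
G0356	1
G0357	1
G0358	0
G0359	0
G0360	1
G0361	0
G0362	1
G0363	1
G0364	0
G0365	1
G0366	0
G0367	0
G0368	1
G0369	0
G0370	1
G0371	0
G0372	1
G0373	1
G0374	0
G0375	1
G0376	0
G0377	0
G0378	1
G0379	0
G0380	0
G0381	0
G0382	0
G0383	0
G0384	1
G0385	0
G0386	0
G0387	0
G0388	0
G0389	1
G0390	1
G0391	1
G0392	1
G0393	1
G0394	0
G0395	1
G0396	0
G0397	0
G0398	1
G0399	1
G0400	1
G0401	1
G0402	0
G0403	1
G0404	1
G0405	0
G0406	1
G0407	1
G0408	0
G0409	0
G0410	0
G0411	0
G0412	1
G0413	0
G0414	1
G0415	0
G0416	0
G0417	1
G0418	0
G0419	0
G0420	0
G0421	0
G0422	1
G0423	0
G0424	0
G0425	0
G0426	1
G0427	0
G0428	1
G0429	0
G0430	1
G0431	0
G0432	1
G0433	0
G0434	0
G0435	0
G0436	0
G0437	0
G0438	0
G0439	0
G0440	0
G0441	1
G0442	0
G0443	1
G0444	0
G0445	0
G0446	1
G0447	0
G0448	1
G0449	1
G0450	0
G0451	0
G0452	0
G0453	0
G0454	1
G0455	0
G0456	0
G0457	0
G0458	0
G0459	0
G0460	0
G0461	0
G0462	1
G0463	1
G0464	0
G0465	1
G0466	1
G0467	0
G0468	0
G0469	0
G0470	1
G0471	0
G0472	0
G0473	1
G0474	1
G0475	1
G0476	0
G0477	0
G0478	1
G0479	0
G0480	1
G0481	0
G0482	0
G0483	0
G0484	0
G0485	1
G0486	1
G0487	0
G0488	0
G0489	0
G0490	0
G0491	0
G0492	0
G0493	0
G0494	0
G0495	0
G0496	0
G0497	1
G0498	0
G0499	1
G0500	0
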