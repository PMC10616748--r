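SET001	planted-module-enriched set	G0013	G0017	G0052	G0069	G0080	G0085	G0096	G0103	G0111	G0113	G0121	G0126	G0132	G0141	G0153	G0155	G0166	G0176	G0204	G0207	G0209	G0210	G0241	G0244	G0251	G0262	G0290	G0301	G0303	G0318	G0344	G0350	G0352	G0354	G0356	G0362	G0365	G0370	G0372	G0375	G0378	G0379	G0402	G0466	G0470	G0474	G0475	G0485
SET002	uniform set	G0003	G0004	G0008	G0015	G0027	G0051	G0072	G0080	G0090	G0100	G0125	G0127	G0130	G0137	G0139	G0148	G0155	G0169	G0209	G0225	G0227	G0240	G0242	G0272	G0316	G0332	G0355	G0374	G0381	G0412	G0420	G0422	G0434	G0466	G0476	G0481
SET003	uniform set	G0009	G0017	G0028	G0061	G0104	G0135	G0141	G0145	G0152	G0155	G0176	G0188	G0206	G0233	G0256	G0262	G0319	G0337	G0350	G0361	G0369	G0372	G0374	G0413	G0423	G0424	G0446	G0450	G0461	G0500
SET004	uniform set	G0062	G0127	G0159	G0191	G0268	G0272	G0295	G0333	G0334	G0335	G0341	G0426	G0463
SET005	uniform set	G0021	G0025	G0030	G0035	G0050	G0058	G0063	G0067	G0068	G0069	G0087	G0110	G0154	G0155	G0163	G0216	G0223	G0224	G0264	G0288	G0303	G0309	G0322	G0349	G0358	G0361	G0395	G0414	G0415	G0427	G0441	G0468	G0474	G0481
SET006	uniform set	G0043	G0061	G0127	G0128	G0222	G0281	G0297	G0333	G0359	G0374	G0419	G0484
SET007	uniform set	G0025	G0026	G0028	G0037	G0056	G0081	G0087	G0113	G0118	G0153	G0156	G0161	G0177	G0204	G0207	G0213	G0261	G0292	G0319	G0330	G0345	G0347	G0363	G0367	G0411	G0432	G0448	G0459	G0475
SET008	uniform set	G0002	G0027	G0033	G0040	G0054	G0055	G0057	G0066	G0079	G0115	G0124	G0126	G0137	G0156	G0162	G0170	G0177	G0179	G0185	G0189	G0216	G0243	G0251	G0255	G0257	G0261	G0269	G0274	G0290	G0305	G0312	G0329	G0344	G0347	G0355	G0357	G0377	G0386	G0394	G0397	G0418	G0429	G0461	G0466	G0472	G0497	G0499
SET009	uniform set	G0001	G0005	G0025	G0031	G0043	G0049	G0066	G0093	G0098	G0103	G0112	G0119	G0124	G0143	G0189	G0214	G0221	G0234	G0250	G0254	G0272	G0299	G0311	G0327	G0366	G0462	G0488	G0500
SET010	uniform set	G0002	G0004	G0007	G0027	G0052	G0070	G0072	G0073	G0074	G0097	G0119	G0129	G0162	G0163	G0164	G0183	G0187	G0188	G0212	G0216	G0281	G0287	G0297	G0299	G0302	G0310	G0317	G0320	G0333	G0336	G0341	G0346	G0347	G0368	G0392	G0397	G0414	G0434	G0455	G0457	G0474	G0475	G0478	G0486	G0488	G0492	G0497	G0498
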