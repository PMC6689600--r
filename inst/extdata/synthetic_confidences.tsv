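question	ind1	ind2	ind3	ind4	ind5	ind6	ind7	ind8
q01	0.0528	0.7163	0.1595	-0.906	-1.3611	1.7391	-0.7196	2.178
q02	3.3656	1.1655	1.8284	1.4169	1.3275	-0.0998	-0.4774	3.2394
q03	-1.1695	-0.2851	3.0489	-0.5977	1.5801	-2.3902	0.2114	2.727
q04	0.0932	-0.7857	0.589	0.3085	1.7345	-0.064	0.6137	1.4513
q05	1.3086	0.0068	1.6466	-1.9638	-0.2166	-1.8953	2.3439	1.7759
q06	0.6674	-0.5258	-1.0262	-0.9002	1.9376	-0.7082	0.9575	-0.5332
q07	0.4728	0.0707	-0.3749	-1.6082	0.7508	-1.104	0.7346	1.5493
q08	-0.5644	-0.7598	-0.7543	1.9159	-0.2503	-0.0588	-2.0095	1.845
q09	1.6884	1.127	2.4585	-1.0221	-0.4545	-1.9639	-2.421	1.229
q10	-0.0701	0.4328	0.9082	-1.7297	-0.1362	-0.6707	0.4464	0.394
q11	0.0286	1.1078	0.113	-1.2321	0.21560000000000001	0.0929	-0.5578	-0.2888
q12	1.3285	0.4461	2.3563	-0.5774	3.0166	-1.0882	-1.7767	1.4054
q13	2.111	-0.2164	2.7623	-0.3433	2.3676	0.492	-1.3773	1.599
q14	1.3952	-1.7964	0.4348	-0.6683	1.6193	-0.4921	0.1353	0.3383
q15	-0.4163	-0.1305	2.8787	-0.0699	-0.3067	-0.8443	2.1606	2.4991
q16	1.101	0.9734	-0.4387	0.951	-0.4832	-0.2427	0.1084	1.4738
q17	2.0266	-0.9405	1.3359	1.3901	-2.2089	1.2315	0.4044	0.2812
q18	0.1555	0.2362	2.387	-1.2746	-0.5893	0.7582	1.4885	3.0613
q19	2.7724	0.4136	3.5174	0.098	1.7206	-1.9945	1.0523	3.6903
q20	2.7125	2.2333	0.5171	-0.5985	0.3039	-0.5212	-2.4018	1.1482
q21	0.0956	0.4639	-0.1002	-0.5313	0.688	0.9064	0.1336	0.2008
q22	0.3624	1.7346	1.718	2.465	-0.9018	-0.3579	-0.4685	2.8754
q23	-0.9069	0.0817	0.4646	-0.4338	-0.6537	-0.5311	0.0626	1.5522
q24	-0.9733	-0.2793	-1.6679	0.8675	1.2434	-1.7185	-0.8742	-0.064
q25	0.4398	-0.7063	-0.1673	0.1625	-0.8532	-1.0839	-2.3723	0.4815
q26	-0.7043	-1.1477	0.7567	-0.1382	-0.5346	0.5433	-2.0948	0.9856
q27	1.4533	0.1706	0.8802	1.7802	1.6585	0.2861	1.2597	2.2821
q28	0.0067	1.2436	2.6215	-0.4208	-0.1465	0.059	-2.1089	3.1881
q29	2.0242	0.0096	0.0971	-1.7273	2.2581	-0.7004	-0.2775	0.143
q30	1.8518	0.598	0.8567	0.4714	-0.3825	-0.2176	1.7707	1.6043
q31	-0.498	1.9146	0.272	-0.8132	1.2695	-0.1674	-0.8297	-1.1249
q32	1.4542	0.5284	1.2492	1.3962	1.806	-1.3762	-1.0658	2.9056
q33	3.6912	0.8596	2.682	1.0318	0.8896	-0.0521	-0.259	3.5879
q34	-1.4514	-0.6333	-1.448	0.4288	0.9266	-1.1316	0.6615	0.8924
q35	0.2459	0.7413	2.712	1.0375	0.0843	0.7333	-0.1093	-1.414
q36	2.2419	-1.4148	0.2403	0.1734	1.1474	-2.7631	1.6638	3.3504
q37	0.4934	0.2405	1.9388	0.053900000000000003	1.6496	-0.0498	0.0476	4.033
q38	0.9796	-0.5586	1.9488	3.0583	1.5629	-0.1887	-0.9851	3.3797
q39	-0.9161	0.6768	-0.2045	0.9815	0.4911	0.0504	-0.9773	1.1979
q40	0.8657	-0.3811	0.8589	-0.2788	0.0146	-0.4372	-2.5416	2.3442
q41	-1.3469	0.041	-0.9078	-1.0024	0.667	0.145	-0.4098	2.1538
q42	0.3819	-0.7162	1.6886	0.2181	0.0648	0.2868	-1.2485	1.2602
q43	0.3318	0.0615	1.5062	0.6707	1.4082	-0.4141	-0.3199	6.1668
q44	1.6664	0.2285	1.1042	1.736	-0.039	-0.6252	0.5364	1.5797
q45	0.8429	0.2057	2.4733	-0.6137	0.4822	-1.7244	-1.305	3.167
q46	-0.6768	0.2493	-0.9553	1.5505	-0.1218	-0.3268	1.1309	0.4883
q47	2.2706	-1.0791	0.1433	-0.9075	0.3522	-0.1902	0.5416	1.5645
q48	1.3216	-1.912	0.3196	2.0179	1.1	0.6757	1.3504	0.7014
q49	1.1862	0.3841	2.694	-0.0763	0.9858	-1.5602	0.2461	1.7972
q50	4.026	2.3796	0.4151	-0.1295	-0.1179	-1.1841	-0.372	3.2365
q51	1.7317	0.3816	-0.0073	1.5063	1.5025	-0.158	0.9416	2.1535
q52	1.0486	-0.2714	1.9889	0.1233	-0.9845	-0.8791	-1.9787	2.0669
q53	-0.3781	-1.0074	1.1264	1.0263	-0.5121	-0.5601	0.3577	1.9664
q54	-1.3637	-1.1003	-0.4023	-1.1719	0.0214	-2.2685	0.2112	0.72
q55	1.0401	-0.1106	0.982	0.4999	2.5787	-1.8945	-0.7716	1.5347
q56	1.208	-1.3345	0.9814	1.2271	-0.2699	1.1155	-0.3558	1.107
q57	0.7795	-0.718	-1.2124	0.0467	0.1656	0.5176	0.455	1.9346
q58	1.5183	2.1321	1.9711	0.9501	-0.5211	-0.3633	-0.984	2.2521
q59	0.0407	1.647	2.6337	0.0068	0.1768	-1.0622	0.5203	3.3239
q60	-1.0046	-0.9302	0.7763	-0.5884	1.4588	0.3019	-0.942	-0.6973
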