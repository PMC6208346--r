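feature	sample-0001	sample-0002	sample-0003	sample-0004	sample-0005	sample-0006	sample-0007	sample-0008	sample-0009	sample-0010	sample-0011	sample-0012	sample-0013	sample-0014	sample-0015	sample-0016	sample-0017	sample-0018	sample-0019	sample-0020	sample-0021	sample-0022	sample-0023	sample-0024
hsa-miR-200c	14.2187	12.8027	14.2411	13.5049	15.5895	12.7116	11.5254	15.1501	13.4135	12.4791	13.558	13.9085	12.4098	13.8145	12.6954	12.4795	12.6111	12.8345	12.9527	11.4963	12.509	12.7813	12.5405	11.6191
hsa-miR-503	2.0688	4.6968	1.084	3.5477	3.4757	2.9656	1.4459	1.0548	2.223	3.3464	2.8332	5.1356	4.4951	3.5317	2.1522	4.9277	3.1404	4.0239	5.1585	3.2025	4.1524	6.89	5.644	3.752
hsa-miR-1307	10.3412	10.77	11.4843	11.1566	11.1885	10.5197	10.513	10.9856	8.9679	12.3241	10.4252	11.273	10.8586	11.5546	8.646	9.2401	7.485	9.6438	9.262	9.9416	9.5481	7.2786	8.2365	8.2869
hsa-miR-361	8.9372	7.6353	8.9448	9.3489	8.1514	8.3777	9.1258	7.6546	7.7787	8.9493	7.4165	7.9644	8.6099	8.2705	8.2507	7.6405	9.171	8.9935	8.1815	7.4965	7.4266	8.4407	8.0229	8.0017
mir-sim-0005	8.6788	7.0326	6.0811	7.4843	6.0805	6.0047	4.8372	6.1619	5.5463	6.4327	5.1128	5.0909	5.7168	7.0202	5.2365	6.558	5.6202	6.4421	8.4226	5.3888	4.9604	7.0304	6.7886	6.039
mir-sim-0006	10.2019	8.9569	9.2685	11.0268	10.4181	10.3261	11.0212	9.9157	10.4236	10.547	9.0324	9.7897	11.4769	10.6814	9.2887	7.7765	10.0478	9.6082	9.3266	10.0222	11.0238	9.8181	9.8168	10.9013
mir-sim-0007	5.4336	5.1774	5.9591	4.0683	7.0615	8.0495	5.4458	6.76	5.323	6.0307	6.2242	6.9936	7.081	5.9884	6.5461	5.4358	6.526	6.0784	6.5002	5.145	5.439	6.5837	6.8317	5.4542
mir-sim-0008	3.4304	4.8266	3.5293	2.9743	4.92	5.5402	5.8102	4.9542	5.7816	4.8386	7.0366	2.0409	4.2476	4.8228	3.2995	4.4946	5.4879	3.0171	3.3309	4.4202	5.3153	4.7693	3.405	4.9249
mir-sim-0009	12.0464	11.1739	12.5296	12.4321	12.5521	12.4815	12.0333	12.7047	12.0111	12.8712	12.3261	12.2428	12.2828	12.3681	12.2383	12.4561	12.1697	12.5189	12.8118	12.5429	12.1842	12.1229	12.2594	12.3072
mir-sim-0010	1.6399	1.4495	1.6996	1.2806	1.7583	2.1264	2.2415	2.1443	1.2834	2.4633	1.4289	1.7753	1.1942	1.7312	2.3949	1.7393	2.0987	1.5497	1.7812	1.0038	1.729	1.5988	1.8993	1.182
mir-sim-0011	12.4256	12.3374	13.0717	11.9903	10.4892	13.1381	12.2439	13.2393	13.0805	13.4044	13.379	12.4753	11.4975	11.9409	13.1071	12.652	12.1046	11.2905	11.8395	12.5265	13.1857	12.828	13.7735	12.8144
mir-sim-0012	13.7649	13.0731	12.8058	13.3876	14.1009	15.0921	12.8673	13.8983	14.4879	13.0556	13.5769	13.8303	14.2495	12.4951	12.4639	13.4378	13.8344	12.907	13.1241	14.0804	14.4426	13.6537	13.2689	13.8374
mir-sim-0013	9.9534	10.6095	10.0743	9.0804	8.9223	9.3486	11.5383	9.6068	9.8268	9.8717	10.4505	9.4802	9.2341	9.9649	10.0734	9.4582	11.3808	9.7557	9.2595	10.245	8.7245	9.6396	9.898	9.4896
mir-sim-0014	9.0592	6.5642	8.7746	5.1403	9.1029	4.371	7.2329	7.8293	6.3235	5.0361	7.6707	7.2694	8.2161	9.299	5.6408	7.8787	5.6478	9.0017	6.6594	8.3149	8.2138	6.18	4.4194	6.5221
mir-sim-0015	7.0763	7.1689	7.5554	5.1069	6.0286	6.8837	5.4867	5.5913	6.7674	5.7235	6.4766	6.4177	6.9273	5.5281	8.1676	5.8357	5.8489	6.1319	6.3451	6.1527	6.0678	5.7947	8.7926	5.3866
mir-sim-0016	11.9792	11.5268	12.0771	11.8247	13.4427	12.2133	10.0456	12.6788	11.6482	13.095	11.8067	12.5949	12.7573	10.5548	13.3244	12.3879	11.3434	11.6185	10.3307	11.5933	13.9536	12.6435	11.9965	10.8947
mir-sim-0017	1.9794	0.6088	1.6562	1.4968	1.6907	1.8645	2.1792	1.5792	1.9168	1.877	1.8802	1.5791	1.0538	1.179	0.8361	1.8216	0.7645	2.2597	1.4981	1.3479	1.9316	1.4114	2.2072	0.9156
mir-sim-0018	13.1853	14.0189	14.9521	14.0589	13.4249	10.8333	13.4398	13.435	9.8588	10.8642	11.2773	12.0671	11.2439	14.219	11.7913	11.4771	12.8499	11.5381	10.4115	11.3704	12.3427	11.5257	10.5449	13.3043
mir-sim-0019	1.4734	0.8786	2.1585	2.2414	2.0331	2.1462	1.3244	2.3547	2.1109	2.1032	2.062	2.3332	1.1717	1.8167	1.8928	2.3826	2.6162	1.5875	2.1616	1.747	1.7019	1.8177	1.744	1.8193
mir-sim-0020	4.0723	3.3649	3.5684	4.8259	4.4565	3.5069	3.4086	4.7493	3.2027	4.5004	3.8925	4.3821	3.6213	5.1817	4.1148	3.9959	4.5406	3.9213	3.2442	4.2875	3.5113	5.1276	2.5432	4.717
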