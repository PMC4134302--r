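gene	control_01	control_02	control_03	control_04	control_05	control_06	control_07	control_08	control_09	control_10	control_11	control_12	control_13	control_14	control_15	control_16	control_17	control_18	control_19	control_20	disease_01	disease_02	disease_03	disease_04	disease_05	disease_06	disease_07	disease_08	disease_09	disease_10	disease_11	disease_12	disease_13	disease_14	disease_15	disease_16	disease_17	disease_18	disease_19	disease_20
g_CL_1_2	10.674	9.5361	11.5689	10.9252	10.639	10.2284	12.4907	11.3941	11.5317	11.2971	11.7695	10.6547	11.2173	10.7657	9.9504	10.755	9.767	12.3184	12.782	10.2733	3.873	6.0477	5.5334	3.5027	5.6303	4.2902	6.6889	5.3129	5.5853	5.6756	4.9286	5.6431	6.9453	3.818	3.6499	5.9095	4.3816	5.2761	3.3117	4.7466
g_CL_2_3	8.5525	8.7444	7.2939	9.5099	7.2798	7.3693	7.6194	6.4959	7.1262	8.1973	8.802	6.8171	6.9509	6.8341	8.046	8.8602	4.8228	7.7335	7.936	8.0967	7.5982	7.6221	7.4579	9.1061	7.9705	8.2764	9.1786	9.5215	7.6225	8.8515	8.1674	7.1685	6.5908	6.7891	6.4293	8.7186	8.4886	7.7648	7.7317	8.461
g_CL_3_4a	4.3251	3.5896	4.7099	6.6199	5.282	4.1697	4.0906	3.4131	4.8132	4.843	4.3031	3.9687	4.9249	4.7602	3.9912	4.3242	3.9152	5.2658	5.6245	5.2149	11.0052	11.5081	11.3377	10.4717	11.0123	11.3075	10.6107	10.1879	10.7695	11.272	11.3946	11.2365	10.8447	12.4107	12.8702	10.9462	11.7306	10.1671	10.4138	10
g_CL_3_4b	5.2144	5.4671	3.5161	6.1532	4.2095	4.4089	4.6619	4.0729	4.7863	6.5366	6.1779	4.9249	3.432	6.1844	4.3438	4.5	5.0608	6.1398	4.0614	5.5185	11.6725	9.9298	10.7621	12.376	10.7085	10.1737	9.9274	11.0511	10.0778	11.0416	10.4704	10.9478	10.503	10.3085	9.5737	13.1531	10.2056	11.3959	10.6745	11.0574
g_R_1_1	11.3108	10.8807	9.8497	10.9224	10.5551	11.9811	9.5881	11.7762	10.796	8.8323	11.5858	11.8286	9.8262	11.2075	11.094	12.832	10.8182	10.0135	9.1673	10.7037	3.5536	4.8558	6.1257	4.0976	6.7056	5.4453	4.6047	4.5119	4.3953	4.831	4.1239	5.9165	6.0038	5.9959	5.5371	5.9581	4.4316	4.3893	2.6514	4.9123
g_R_1_2	12.174	11.4672	10.7255	9.1811	12.365	10.3384	11.2175	10.2193	12.7197	11.5984	10.5331	9.964	8.8517	10.9564	11.0179	10.6707	11.3413	10.3263	10.0985	10.648	3.8564	3.9883	5.2047	4.8122	3.5318	4.4505	4.155	3.6605	5.0643	6.5883	3.8154	4.6304	4.4891	5.7674	5.0486	4.4907	5.7786	2.9163	3.7785	4.5452
g_R_1_3	11.6188	11.4981	11.5779	9.9626	11.4975	10.2276	11.6701	9.7214	11.202	11.0431	11.3856	10.8528	11.3417	10.0289	9.3965	11.2613	12.1068	9.0953	10.0491	11.1337	4.6992	6.243	4.9841	4.1297	5.2349	3.557	4.3441	4.0642	4.3413	6.3968	4.4108	5.265	5.1274	5.5071	4.734	4.4324	4.8432	5.7298	7.1105	6.4565
g_R_1_4	10.8873	11.8949	9.6031	11.3025	10.1856	8.9815	10.7121	10.9986	11.5127	12.295	10.4654	10.7185	11.905	11.5742	11.4831	9.8878	11.6888	10.2821	10.1647	10.7731	3.6111	4.9211	5.1852	5.2426	4.4909	4.7752	2.493	4.1251	3.9457	3.9541	5.1809	4.5611	5.2391	4.8789	3.4788	6.5003	3.1894	3.2827	4.684	6.6188
g_R_2_1a	8.917	8.2792	8.7491	6.7221	8.2681	7.4664	8.4693	6.149	9.4524	8.7063	9.0567	6.6263	9.0965	6.7401	7.7756	9.0622	8.471	7.6165	8.5461	8.8631	5.9725	7.1927	8.1082	9.2183	5.8838	8.3015	8.1678	7.1676	6.467	8.1168	8.1457	6.8409	8.1622	8.9325	7.3785	7.2282	6.0972	8.2875	7.9435	7.0711
g_R_2_1b	7.7767	9.0079	6.9488	8.1383	7.4078	8.4347	7.5299	8.4515	8.3639	8.3455	7.7939	9.5585	6.5287	9.0617	7.5626	8.205	6.3599	7.6795	9.6125	9.6042	8.5052	7.0038	8.674	7.0198	8.5639	8.1746	9.2156	7.7869	8.4066	8.1056	8.7557	7.7359	8.3648	6.5203	7.5867	8.1555	10.337	7.6483	9.4286	7.6893
g_R_2_2	8.5264	5.9269	8.1654	7.949	10.1335	7.2288	7.7607	7.5671	7.1242	7.9201	8.607	7.4251	7.7194	7.566	9.3278	5.9757	7.321	5.9081	7.3469	7.5542	8.7715	7.1417	7.048	8.5596	9.789	7.4172	8.2551	7.8515	8.3519	7.932	8.0278	7.5006	7.4491	6.6288	7.933	7.9585	7.5381	8.7405	9.1552	9.009
g_R_2_3	7.2052	9.1899	9.1298	9.8521	9.1727	7.2461	7.5525	8.7136	7.9854	8.4548	7.4519	10.1873	8.8461	8.2392	7.5315	9.2274	8.4863	6.1482	7.9634	6.8104	6.3871	7.0493	7.5015	8.7204	8.0532	7.771	9.6191	7.9242	6.2692	7.6845	8.1447	8.8246	7.4056	8.4393	7.8122	7.7482	8.5472	6.968	8.571	7.8723
g_R_2_4	9.4278	7.2756	9.1737	9.1117	8.7468	7.7006	7.3812	8.9607	7.2755	9.2763	5.9	8.7943	6.7141	7.4977	6.66	9.1953	8.2262	8.4397	7.8894	8.2466	9.1424	6.8782	7.3465	6.2234	8.9129	8.9954	7.9959	7.3779	7.8112	8.4833	7.7624	7.4675	7.1106	8.453	7.8176	9.1192	8.4246	8.5619	8.4096	7.8007
g_R_3_1	3.5332	5.168	4.5721	4.4886	4.7695	6.664	5.253	5.3815	6.9694	6.2648	5.2508	5.2026	4.6876	3.2961	6.6654	5.7725	4.3533	5.1419	6.242	4.2385	13.0983	10.8649	10.8739	11.2241	10.8535	11.7025	11.3148	11.4535	9.6002	11.5122	10.2572	10.6194	9.8373	10.7187	10.7171	11.5563	9.7813	12.3013	11.1935	11.6257
g_R_3_2	4.7633	5.9203	4.7402	4.4561	5.0878	3.7557	4.2466	6.2181	4.4636	5.2693	4.9451	4.9779	4.6372	5.5238	5.5389	3.5905	4.8867	4.1749	4.3076	4.606	10.8326	10.1259	10.3621	9.86	10.8238	9.9309	11.1649	12.1348	11.1768	10.0519	11.2609	9.8244	10.5392	9.7049	10.7573	10.9319	10.5492	11.4747	11.6473	12.0802
g_R_3_3	4.8067	3.3284	3.5888	3.2711	2.8163	4.2169	5.7323	4.9829	4.9738	4.8795	4.3403	5.3045	6.4125	6.5642	5.9994	4.5676	5.5205	3.6288	3.8346	3.2717	10.7331	11.2587	11.3376	12.3769	9.9445	10.8844	10.2873	9.7108	11.4528	11.7699	11.4294	8.2339	11.1217	10.0335	9.7031	12.031	10.0786	10.3531	9.6199	10.5376
g_R_3_4	4.1502	5.4485	4.3586	5.4707	4.5334	5.2448	4.5974	4.9618	4.836	5.7953	3.5441	3.8908	4.7448	2.5337	5.3415	4.5577	7.5867	5.0249	3.9439	5.2629	11.7948	9.2549	10.9707	12.7801	12.2391	11.6924	9.7234	11.1374	10.1467	11.3091	12.565	10.7482	12.6209	10.4845	11.5044	11.2642	10.2408	10.8955	12.002	12.6581
g_R_4_1a	8.0585	8.4825	8.1125	8.0054	9.686	7.8561	5.177	9.2437	6.6167	7.486	8.0237	8.7655	8.387	7.8512	6.9414	9.349	8.5422	9.581	8.7235	6.3844	7.5432	6.7276	9.2287	8.2941	9.1278	6.3281	9.0681	7.8359	8.9272	8.3059	9.4976	9.6662	7.9689	9.1665	8.4312	8.2632	8.17	8.7052	7.4307	8.7003
g_R_4_1b	7.1823	8.7582	8.4226	9.348	7.4321	6.3914	8.463	7.0441	8.4235	7.5934	8.5479	7.978	8.5249	10.1108	7.9584	6.9254	9.0652	7.2403	8.3602	7.8827	7.0283	7.3369	9.5853	7.0684	7.3145	8.1602	7.1971	7.9813	8.0281	7.7484	7.2647	7.9119	7.7208	9.0452	6.5403	7.9362	8.4116	10.2655	9.4816	7.5326
g_R_4_2	5.9497	5.6807	8.3868	8.7241	7.9533	8.9516	10.1329	8.9154	7.2095	9.2197	7.1911	7.096	8.6151	7.6538	6.7072	7.6649	7.2499	7.4615	8.2562	8.3259	7.5275	7.7035	7.6856	8.6356	9.7541	7.2253	7.1568	7.7852	8.356	8.1189	8.2534	6.7529	6.713	7.2093	8.3015	8.2064	6.2483	8.2868	8.6679	7.8141
g_R_4_3	7.8362	7.5405	7.3122	9.5525	7.843	6.1809	7.7295	7.0607	9.2099	8.0837	7.761	8.4	7.6672	8.9822	7.1061	8.7508	8.7938	7.7397	8.7529	6.0991	8.9477	7.426	8.9758	7.1642	8.2859	8.1155	9.4351	9.0496	9.2735	6.4703	7.1837	8.4194	9.2136	7.8031	8.3065	8.4249	8.5932	8.2951	8.8231	8.916
g_R_4_4a	8.7085	6.8946	8.1489	9.3255	9.6022	9.7837	8.2485	8.1121	8.8945	8.5899	7.6469	6.8507	8.7453	8.3914	8.5419	9.9972	7.2502	7.3554	7.0074	7.5302	9.016	7.9738	8.7421	6.9801	7.9038	6.961	7.0226	6.2186	7.5875	8.5253	9.2265	10.0375	7.752	8.6611	8.3734	7.2657	7.9662	9.4115	8.4463	9.0184
g_R_4_4b	7.732	8.4029	7.9424	7.9657	8.7687	9.8871	8.0381	8.553	7.8988	7.4826	8.8196	8.1882	7.6887	7.49	8.9696	9.7919	8.3063	9.2153	9.4863	8.1238	9.7519	8.2597	10.2255	8.1615	8.536	8.1776	8.2838	7.7684	7.6891	8.8645	8.6345	6.5585	7.5264	4.8737	7.7591	8.3536	7.3584	6.9399	9.537	6.1937
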