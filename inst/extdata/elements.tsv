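symbol	z	weight	r_vdw	r_cov	cm_a1	cm_a2	cm_a3	cm_a4	cm_b1	cm_b2	cm_b3	cm_b4	cm_c	fp_cu	fpp_cu	fp_mo	fpp_mo	mu_rho_cu	mu_rho_mo
H	1	1.0079	1.2	0.31	0.493002	0.322912	0.140191	0.04081	10.5109	26.1257	3.14236	57.7997	0.003038	0.0	0.0	0.0	0.0	0.0	0.0
B	5	10.811	1.92	0.84	2.0545	1.3326	1.0979	0.7068	23.2185	1.021	60.3498	0.1403	-0.1932	0.0093	0.0039	0.0016	0.0007	1.904	0.1516
C	6	12.0107	1.7	0.73	2.31	1.02	1.5886	0.865	20.8439	10.2075	0.5687	51.6512	0.2156	0.0179	0.0091	0.0031	0.0016	3.9512	0.3237
N	7	14.0067	1.55	0.71	12.2126	3.1322	2.0125	1.1663	0.0057	9.8933	28.9975	0.5826	-11.529	0.0311	0.0181	0.0061	0.0033	6.7461	0.5681
O	8	15.9994	1.52	0.66	3.0485	2.2868	1.5463	0.867	13.2771	5.7011	0.3239	32.9089	0.2508	0.0495	0.0323	0.0109	0.0061	10.5615	0.9145
F	9	18.9984	1.47	0.57	3.5392	2.6412	1.517	1.0243	10.2825	4.2944	0.2615	26.1476	0.2776	0.0732	0.0534	0.0176	0.0103	14.7203	1.3086
Na	11	22.9898	2.27	1.66	4.7626	3.1736	1.2674	1.1128	3.285	8.8422	0.3136	129.424	0.676	0.1358	0.1241	0.0367	0.025	28.2438	2.6241
Mg	12	24.305	1.73	1.41	5.4204	2.1735	1.2269	2.3073	2.8275	79.2611	0.3808	7.1937	0.8584	0.1729	0.1774	0.0496	0.0365	38.1915	3.6203
Al	13	26.9815	1.84	1.21	6.4202	1.9002	1.5936	1.9646	3.0387	0.7426	31.5472	85.0886	1.1151	0.2128	0.2459	0.0643	0.0516	47.6932	4.6112
Si	14	28.0855	2.1	1.11	6.2915	3.0353	1.9891	1.541	2.4386	32.3337	0.6785	81.6937	1.1407	0.2549	0.3307	0.0826	0.0707	61.6146	6.0693
P	15	30.9738	1.8	1.07	6.4345	4.1791	1.78	1.4908	1.9067	27.157	0.526	68.1645	1.1149	0.2958	0.4342	0.1026	0.0946	73.351	7.3698
S	16	32.065	1.8	1.05	6.9053	5.2034	1.4379	1.5863	1.4679	22.2151	0.2536	56.172	0.8669	0.3332	0.5575	0.125	0.1239	90.9879	9.3223
Cl	17	35.453	1.75	1.02	11.4604	7.1964	6.2556	1.6455	0.0104	1.1662	18.5194	47.7784	-9.5574	0.3647	0.7028	0.1495	0.1591	103.7418	10.8252
K	19	39.0983	2.75	2.03	8.2186	7.4398	1.0519	0.8659	12.7949	0.7748	213.187	41.6841	1.4228	0.3876	1.0672	0.2023	0.2504	142.8352	15.4479
Ca	20	40.078	2.31	1.76	8.6266	7.3873	1.5899	1.0211	10.4421	0.6599	85.7484	178.437	1.3751	0.3648	1.2873	0.2278	0.3076	168.0817	18.5127
Sc	21	44.9559	2.11	1.7	9.189	7.3679	1.6409	1.468	9.0213	0.5729	136.108	51.3531	1.3329	0.3124	1.5353	0.2533	0.373	178.7161	20.0153
Ti	22	47.867	1.95	1.6	9.7595	7.3558	1.6991	1.9021	7.8508	0.5	35.6338	116.105	1.2807	0.2191	1.8093	0.2792	0.4474	197.803	22.5443
V	23	50.9415	1.06	1.53	10.2971	7.3511	2.0703	2.0571	6.8657	0.4385	26.8938	102.478	1.2199	0.0685	2.1125	0.3025	0.5314	217.0083	25.1627
Cr	24	51.9961	1.13	1.39	10.6406	7.3537	3.324	1.4922	6.1038	0.392	20.2626	98.7399	1.1832	-0.1643	2.4471	0.3233	0.6259	246.2777	29.0374
Mn	25	54.938	1.19	1.39	11.2819	7.3573	3.0193	2.2441	5.3409	0.3432	17.8674	83.7543	1.0896	-0.533	2.8087	0.3384	0.731	267.5394	32.0967
Fe	26	55.845	1.26	1.32	11.7695	7.3573	3.5222	2.3045	4.7611	0.3072	15.3535	76.8805	1.0369	-1.1389	3.2014	0.3494	0.8475	299.9947	36.606
Co	27	58.9332	1.13	1.26	12.2841	7.3409	4.0034	2.3488	4.2791	0.2784	13.5359	71.1692	1.0118	-2.3847	3.6197	0.3523	0.9757	321.4143	39.9354
Ni	28	58.6934	1.63	1.24	12.8376	7.292	4.4438	2.38	3.8785	0.2565	12.1763	66.3421	1.0341	-2.9787	0.5098	0.3421	1.1163	45.456	45.8805
Cu	29	63.546	1.4	1.32	13.338	7.1676	5.6158	1.6735	3.5828	0.247	11.3966	64.8126	1.191	-1.956	0.5897	0.3222	1.2696	48.5606	48.194
Zn	30	65.38	1.39	1.22	14.0743	7.0318	5.1652	2.41	3.2655	0.2333	10.3163	58.7097	1.3041	-1.5423	0.6787	0.2861	1.4351	54.3262	52.9501
Br	35	79.904	1.85	1.2	17.1789	5.2358	5.6377	3.9851	2.1723	16.5796	0.2609	41.4328	2.9557	-0.6684	1.2823	-0.2908	2.4676	83.9821	74.4959
I	53	126.9045	1.98	1.39	20.1472	18.9949	7.5138	2.2735	4.347	0.3814	27.766	66.8776	4.0712	-0.301	6.8427	-0.4442	1.8166	282.1649	34.5309
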