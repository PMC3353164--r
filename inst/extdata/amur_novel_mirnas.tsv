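id	sequence	reads	stem_loop_length	start_in_chr	mfe	star
va-miR001	TTTTTTTATTGGATCCGTCGGGA	108	84	13:9154663	-21.4	N
va-miR002	TTTTGTTTTTATTGTTGTTTT	14	240	16:6817573	-42.05	N
va-miR003	TTTTCTTTTCCTGCATTTTCT	21	196	10_random:812676	-28.77	N
va-miR004	TTTTCCTATGATTTCTTGGCA	18	139	17:4715183	-44.23	N
va-miR005	TTTGCATGAGGGGGGATTGTCAT	8	160	14:10210052	-55.9	N
va-miR006-1	TTTCTTAGCAACCAAACAGAG	10	213	3:3982162	-36.6	N
va-miR006-2	TTTCTTAGCAACCAAACAGAG	8	213	3:3995013	-36.6	N
va-miR006-3	TTTCTTAGCAACCAAACAGAG	8	255	19:4998280	-74.2	N
va-miR007	TTTCCGACTCGCACTCATGCCGT	812	103	17:5737883	-49	Y
va-miR008	TTTCCACGGCTTTCTTGAACT	16273	182	1:1942578	-57.1	Y
va-miR009	TTTCCACATCTTTCTTGAACT	10	113	12:7648535	-49.5	Y
va-miR010	TTTAATTTAAATATTGAAGAT	13	220	8:10844562	-43.6	N
va-miR011	TTGTCGCAGGAGAGACGGCACT	6	92	14:17492727	-57.8	Y
va-miR012	TTGGCACATTATCTAACAACT	14	107	8:2707092	-21.1	N
va-miR013	TTGCTGAGAGAGTCGTCTGCC	53	81	9:13023036	-38.5	Y
va-miR014	TTGCTAAATCTTTGATTCGATC	20	103	13:10216545	-37.52	N
va-miR015	TTGCTAAATCATTGATTCGATC	11	101	13:10213352	-34.2	Y
va-miR016	TTCTTGTGATCTTGTTGTTTC	9441	148	5:20754701	-88.9	N
va-miR017	TTCTTCTTAACGTCTGACTTA	10	135	1:1002143	-57.6	N
va-miR018	TTCTCGGACCAGGCTTCATTC	148	161	7:14570131	-64.3	N
va-miR019	TTCAAGTCAAAGTCGAACAAG	16	71	1:15194533	-20.2	N
va-miR020	TTATTAACCATTTAAATTTA	5	212	4:14934239	-21.55	N
va-miR021	TTATGTGAGTGTTCGGCAAATC	16	90	5:20305533	-37.9	N
va-miR022-1	TTAGTTTGAACTAGGAGATGACA	10	113	10:6246751	-20.8	N
va-miR022-2	TTAGTTTGAACTAGGAGATGACA	10	255	10:6328614	-49.9	N
va-miR023	TTAGATGATCATCAACAAACA	9128	118	5:23154645	-45.5	Y
va-miR024	TTACTTTTATCTGAATAGAAA	8	108	15:3408926	-26.7	N
va-miR025	TTACACAGAGAGATGACGGTGG	633	105	5:6660435	-50.04	Y
va-miR026	TGGTAAATTGGTTTAAATATTC	11	192	18:19596668	-22.4	N
va-miR027	TGGATGCATGTAGCTTGTCAA	21	103	18:4024355	-71.9	N
va-miR028	TGGATACACTTTTTATTTTTT	6	204	10:2463091	-29.5	N
va-miR029-1	TGGAGAAGGGGAGCACGTGCA	5	118	14:1404606	-59	N
va-miR029-2	TGGAGAAGGGGAGCACGTGCA	6	119	7:3651397	-45.9	N
va-miR030	CGCCGCTCTCCTGTGACAAGA	6	92	14:17492727	-57.8	N
va-miR031	TGCATTTGCACCTGCACCTTA	104	165	6:22063225	-75.22	Y
va-miR032	TGATTGTAGAAAATGTTTTTAAC	5	111	6:21035897	-36.7	N
va-miR033	TGATATTAGCAGCTGAGAACA	10	147	14:11536480	-70	Y
va-miR034	TGAGTAGTGGACTATCGCATG	9	116	17:7362816	-43.9	N
va-miR035	TGAGGAAGGGTGTTAGAGTAC	13	90	13:5595054	-46.1	N
va-miR036	TGACCGGCTCTTATCTCTCATG	27	189	17:351716	-79.3	Y
va-miR037	TGACACTATATAAATATGAA	6	244	2:8067706	-48.1	N
va-miR038	TGAATGGTTGGTAAATTGAG	11	150	12:14954776	-40.6	N
va-miR039	TGAAATGTAGGCAAGGAAAAG	9	192	16:8071148	-53.6	N
va-miR040	TCTGTTTGGACGCCGAGAAAA	7	217	17:10557309	-62.22	N
va-miR041	TCTGTCGCAGGAGAGATGATGC	30	103	14:17809215	-53.9	Y
va-miR042	TCTGTACTTTAAGAATCTGGCTT	15	208	15:6195235	-41.2	Y
va-miR043	TCTGCATTTGCACCTGCACCT	15	165	8:17999572	-57.1	N
va-miR044	TCTCTTGATATTAGTAGCTGA	9	138	14:11536485	-71.9	N
va-miR045	TCGAGTGGGAACGCATTGAGC	6	150	12:13192937	-35.7	N
va-miR046	TCCCAGGAGAGATGGCACCTGC	330	85	17:5984990	-43	N
va-miR047	TCACAAGTTCATCCAAGCACCA	32758	136	18_random:5237347	-51.87	Y
va-miR048	TCAATTAGTAGCTTAACATGG	8	132	11:5115765	-58.49	N
va-miR049	TCAATAAGGTACTTTTAGCT	108	126	11:12939237	-34.3	Y
va-miR050	TCAACTTGATTTTTGGATGAG	9	101	8:15743876	-27.8	N
va-miR051	TCAAAAGAGAAAATGTGGATG	46	100	6:4462385	-35.9	N
va-miR052	TATTAAGTTCAAGTGAAAATT	5	206	10_random:1196749	-64.5	N
va-miR053	TAGTGATTTTAGGAAGCGTTT	7	271	16:432019	-45.26	N
va-miR054	TAGGAAACGTTTCTACTCTTT	20	311	scaffold_1047:19353	-59.7	N
va-miR055	TAATCTGCATCCTGAGGTCTA	48	107	8:14329491	-44.9	Y
va-miR056-1	TAAAATCACTATCAAACGAA	15	133	10:1636145	-21	N
va-miR056-2	TAAAATCACTATCAAACGAA	13	134	11:1222860	-21.2	Y
va-miR056-3	TAAAATCACTATCAAACGAA	12	132	14:9946665	-25.85	N
va-miR056-4	TAAAATCACTATCAAACGAA	13	255	16_random:3940513	-39.5	N
va-miR056-5	TAAAATCACTATCAAACGAA	15	136	8:11389633	-33.7	N
va-miR057-1	GTTGGAAGTCGGTGGGGGACC	7884	91	19:13455035	-47.9	Y
va-miR057-2	GTTGGAAGTCGGTGGGGGACC	7884	92	19_random:737237	-42.6	Y
va-miR058	GTAGCATCATCAAGATTCACA	14	108	6:21821956	-46.5	N
va-miR059	GGAATCTTGATGATGCTGCAT	18	152	6:5961963	-69.27	Y
va-miR060	GAACATCCAGATCATAGGTATGA	9	276	13:6835040	-49.2	N
va-miR061	CTTCAGTGAGTGTGGCGTCAACG	8	155	1_random:4350301	-56.26	N
va-miR062	CTATGTTATAGGATCTTGGAT	315	99	10:1456140	-51.8	Y
va-miR063	CTAGGAAGCGTTTTTAATATT	6	99	8:910651	-38.93	N
va-miR064	CTAAAATCATTGTCAAACGAG	12	303	scaffold_352:50742	-54.8	N
va-miR065-1	CTAAAATCACTACCAAACGG	10	99	1:15345941	-23	N
va-miR065-2	CTAAAATCACTACCAAACGG	9	129	7:12853717	-24.2	N
va-miR066	CGTCTTTTAAATTTTTTTATC	6	121	7:11538839	-19.7	N
va-miR067	CGGGAGATGACTACTGGAAG	8	106	17:2382956	-60.1	N
va-miR068	CGCTATCCATCCTGAGTTTCA	375	122	8:8483671	-54.4	N
va-miR069	CGCCGCTCTCCTGTGACAAGA	6	92	14:17492727	-57.8	N
va-miR070	CCAAGAGGGTGGAGTTCAGA	10	111	14:13763190	-54.9	N
va-miR071	CATGTGCCCCTCTTCCCCATC	5	168	8:8981156	-60.21	N
va-miR072	CATGGGCGGTTTGGTAAGAGG	26555	117	1:3849422	-46.2	Y
va-miR073	CATGACAAAAGATACTTCATT	19	95	6:9332049	-64.1	N
va-miR074	CAGGTTTATTGTTTTTTAATT	7	95	1_random:3034469	-22	N
va-miR075	CAGGAAAGTCAGGGAAGTGTA	9	93	13:6656017	-41.93	Y
va-miR076	CAAGTGTGGGATTTTGGGTGGCT	14	187	4:15148566	-59.2	N
va-miR077	ATTTCATCATTATATAAAACG	5	260	2:10655532	-124.6	N
va-miR078	ATTGACATCGTCTAACATAA	27	96	13:908030	-37.2	N
va-miR079	ATTATTTTTTTTCATGGGAA	7	183	6:4945482	-40.4	N
va-miR080	ATTATATGTGTGAGCCGTTCA	39	97	19:13648253	-23.2	N
va-miR081	ATCATGTAGATATTGTCCGCT	21	216	18:11023560	-77.4	N
va-miR082	ATATTATTAGGGAATTAAGT	4	82	18:15863697	-19.7	N
va-miR083	ATACCATGTGGAAAAGAGGAATC	89	199	16:2126243	-38.7	N
va-miR084	ATAAAACAGGGCATAATTAG	90	162	8:3276798	-27.3	N
va-miR085-1	AGGGAAGGTCCCGTTGAGTT	8	87	3:4651805	-34.8	N
va-miR085-2	AGGGAAGGTCCCGTTGAGTT	11	80	scaffold_389:33261	-31	N
va-miR086	AGAGCCAAATATACTCCGCGG	19	83	9:402800	-52.1	N
va-miR087-1	AGAATGTGTTTGATAGTAATT	7	220	13:10609418	-32.71	N
va-miR087-2	AGAATGTGTTTGATAGTAATT	7	152	3:9026582	-32.9	N
va-miR087-3	AGAATGTGTTTGATAGTAATT	7	134	5:8615567	-39.8	N
va-miR087-4	AGAATGTGTTTGATAGTAATT	7	99	7:6125455	-19.4	N
va-miR088	AGAAGAGAGAGAGTACAGCTA	27	259	5:17354630	-65.6	N
va-miR089	AGAAGAACAAGTAGACTGAGC	11	95	12:17274522	-35.6	N
va-miR090	AGAAAACTGTTTTTAAAAACT	25	209	3:3268552	-33.5	N
va-miR091	AAGTGGTGCTGTCTAGGGTAT	8	153	16_random:2298331	-74.9	N
va-miR092	AAGGTTACGAAGAATGTGAG	7	65	6:20373849	-28.4	Y
va-miR093	AAGGGTTTCTCACAGAGTTTA	40	135	18:1385784	-66.9	N
va-miR094	AACTAACATAACTAAAGTGAA	21	78	18:7824675	-25	N
va-miR095	AACAAATGCTTGATTAAATG	7	185	16:3892094	-46.34	N
va-miR096	AAATTTGATTTTATGGTATT	14	277	1:4778703	-52.3	N
va-miR097	AAATTGGCTCTGTAAATTTC	14	137	18:3503665	-77.6	Y
va-miR098	AAATTGACCTATTTAATAACT	6	225	13:6487398	-33.8	N
va-miR099-1	AAATAGAACAAAACACAGCAA	8	101	4:15872785	-57.2	N
va-miR099-2	AAATAGAACAAAACACAGCAA	8	101	scaffold_477:40535	-63.2	N
va-miR100	AAAGTGCATTTGATAGTGATTC	5	142	19_random:164412	-29.22	Y
va-miR101	AAAAATGAAAATGGGAGTCGGT	11	243	5:12357599	-42.41	N
va-miR102	AAAAAGTTTGTCAAATATTG	15	97	19:13648253	-23.2	N
va-miR103	AAAAAATTCAAAGGGAAATC	8	162	2:2995078	-26.63	N
va-miR104	GGAATGGATGGTTAGGAGAG	2136	NA	17:5578270	-54.4	Y
va-miR105	TAAAAGATAGGGATCGGATGGAG	6	192	14:15112983	-59.2	N
va-miR106	GTTGGAAGTCGGTGGGGGACC	4330	91	19:13455035	-47.9	N
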