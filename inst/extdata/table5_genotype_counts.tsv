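snp_id	group	controls_0	cases_0	controls_1	cases_1	controls_2	cases_2
rs10406069	nontumor	767	737	350	330	56	48
rs1053047	nontumor	321	323	591	544	261	248
rs1053667	nontumor	1058	998	115	117	NA	NA
rs12232826	nontumor	1087	1026	86	89	NA	NA
rs1378940	nontumor	502	501	520	476	151	138
rs1527423	nontumor	332	299	574	557	267	259
rs1559931	nontumor	659	652	441	395	73	68
rs16848494	nontumor	1125	1063	48	52	NA	NA
rs17703261	nontumor	776	711	353	369	44	35
rs17797090	nontumor	981	939	192	176	NA	NA
rs1943676	nontumor	506	499	526	498	141	118
rs4404254	nontumor	658	652	442	395	73	68
rs720607	nontumor	362	364	574	547	237	204
rs7628626	nontumor	805	726	336	351	32	38
rs7683093	nontumor	856	823	291	265	26	27
rs7911488	nontumor	533	504	524	491	116	120
rs8176318	nontumor	560	484	504	504	109	127
rs8679	nontumor	704	684	414	373	55	58
rs9874	nontumor	885	837	265	255	23	23
rs999885	nontumor	327	298	577	555	269	262
rs10508445	differential	307	303	566	555	300	257
rs1062707	differential	680	671	414	379	79	65
rs11068503	differential	366	339	555	544	252	232
rs1332793	differential	462	433	542	522	169	160
rs13505	differential	623	609	450	427	100	79
rs17281995	differential	848	809	304	277	21	29
rs2043556	differential	737	707	374	366	62	42
rs2228043	differential	898	841	275	274	NA	NA
rs2270841	differential	637	577	454	445	82	93
rs2288024	differential	1080	1046	93	69	NA	NA
rs2298209	differential	1132	1088	41	27	NA	NA
rs2344843	differential	472	467	529	499	172	149
rs2693737	differential	968	913	205	202	NA	NA
rs276466	differential	720	642	385	419	68	54
rs2909339	differential	871	792	278	295	24	28
rs353292	differential	341	309	609	573	223	233
rs353293	differential	340	310	610	572	223	233
rs8905	differential	928	836	234	256	11	23
rs9304994	differential	380	386	599	534	194	195
rs1057560	both	316	308	590	555	267	252
rs2910164	both	665	652	439	405	69	58
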