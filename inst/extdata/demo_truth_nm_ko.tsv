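molecule	position	fraction
18S	174	0.979
18S	183	0.902
18S	264	0.865
18S	289	0.859
18S	337	0.882
18S	354	0.31
18S	377	0.894
18S	385	0.976
18S	389	0.872
18S	425	0.91
18S	436	0.872
18S	473	0.88
18S	510	0.95
18S	545	0.863
18S	569	0.909
18S	576	0.64
18S	717	0.923
18S	754	0.851
18S	867	0.82
18S	879	0.891
18S	925	0.933
18S	951	0.01
18S	977	0.98
18S	979	0.968
18S	995	0.979
18S	1000	0.14
18S	1031	0.932
18S	1034	0.914
18S	1141	0.976
18S	1272	0.6
18S	1325	0.938
18S	1362	0.884
18S	1365	0.874
18S	1391	0.874
18S	1440	0.899
18S	1595	0.96
18S	1639	0.49
18S	1690	0.953
18S	1696	0.959
18S	1757	0.909
18S	1830	0.954
28S	79	0.9
28S	205	0.949
28S	208	0.907
28S	273	0.968
28S	327	0.892
28S	347	0.861
28S	365	0.956
28S	424	0.967
28S	473	0.976
28S	499	0.924
28S	585	0.944
28S	593	0.951
28S	750	0.932
28S	856	0.944
28S	902	0.9
28S	1031	0.871
28S	1253	0.874
28S	1323	0.901
28S	1359	0.886
28S	1384	0.875
28S	1400	0.916
28S	1881	0.949
28S	2069	0.94
28S	2075	0.04
28S	2217	0.936
28S	2315	0.911
28S	2326	0.913
28S	2328	0.894
28S	2341	0.905
28S	2401	0.87
28S	2639	0.928
28S	2694	0.959
28S	2702	0.931
28S	2721	0.867
28S	2787	0.924
28S	2861	0.79
28S	2876	0.54
28S	2937	0.931
28S	2951	0.971
28S	3021	0.966
28S	3033	0.964
28S	3156	0.881
28S	3170	0.946
28S	3256	0.9
28S	3397	0.86
28S	3454	0.862
28S	3593	0.949
28S	3698	0.895
28S	3712	0.904
28S	3718	0.895
28S	3749	0.851
28S	3757	0.969
28S	3770	0.874
28S	3812	0.944
28S	3867	0.924
28S	3893	0.92
28S	3904	0.896
28S	4042	0.63
28S	4130	0.874
28S	4247	0.902
28S	4456	0.913
28S	4676	0.915
28S	4682	0.9
28S	4769	0.934
28S	4780	0.895
28S	4820	0.974
28S	5008	0.856
5.8S	14	0.95
5.8S	75	0.876
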