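molecule	position	fraction
18S	29	0.939
18S	100	0.902
18S	193	0.858
18S	232	0.946
18S	242	0.931
18S	296	0.932
18S	395	0.924
18S	428	0.953
18S	478	0.874
18S	553	0.958
18S	554	0.919
18S	558	0.912
18S	566	0.923
18S	579	0.879
18S	608	0.942
18S	634	0.892
18S	664	0.949
18S	681	0.871
18S	697	0.931
18S	786	0.864
18S	849	0.963
18S	860	0.951
18S	892	0.951
18S	897	0.916
18S	928	0.964
18S	1012	0.935
18S	1046	0.967
18S	1116	0.955
18S	1278	0.949
18S	1336	0.955
18S	1395	0.937
18S	1406	0.917
18S	1420	0.873
18S	1496	0.923
18S	1497	0.885
18S	1527	0.943
18S	1539	0.875
18S	1618	0.97
18S	1660	0.857
18S	1708	0.976
18S	1719	0.862
18S	1744	0.967
18S	1795	0.874
18S	1801	0.876
28S	94	0.888
28S	106	0.954
28S	146	0.912
28S	223	0.95
28S	391	0.979
28S	421	0.955
28S	526	0.932
28S	562	0.96
28S	698	0.915
28S	799	0.936
28S	871	0.917
28S	889	0.918
28S	897	0.895
28S	914	0.955
28S	1166	0.878
28S	1269	0.905
28S	1536	0.899
28S	1582	0.77
28S	1779	0.92
28S	1903	0.945
28S	2036	0.899
28S	2124	0.943
28S	2167	0.855
28S	2264	0.915
28S	2302	0.944
28S	2469	0.977
28S	2539	0.973
28S	2548	0.888
28S	2801	0.884
28S	2810	0.97
28S	2816	0.945
28S	2839	0.29
28S	2843	0.927
28S	3038	0.86
28S	3465	0.954
28S	3486	0.884
28S	3734	0.92
28S	3776	0.943
28S	3822	0.85
28S	3884	0.941
28S	3960	0.858
28S	4023	0.907
28S	4059	0.893
28S	4080	0.968
28S	4160	0.907
28S	4220	0.9
28S	4241	0.941
28S	4254	0.964
28S	4312	0.91
28S	4329	0.907
28S	4341	0.911
28S	4381	0.963
28S	4411	0.866
28S	4420	0.72
28S	4579	0.32
28S	4636	0.909
28S	4673	0.79
28S	4763	0.902
28S	4852	0.959
28S	4973	0.917
28S	5001	0.77
5.8S	55	0.894
5.8S	69	0.954
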