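molecule	position	residue	mod_type	guides	legacy_position
18S	29	U	Psi	Unknown	
18S	100	U	Psi	Unknown	
18S	193	U	Psi	Unknown	
18S	232	U	Psi	Unknown	
18S	242	U	Psi	Unknown	
18S	296	U	Psi	Unknown	
18S	395	U	Psi	Unknown	
18S	428	U	Psi	Unknown	
18S	478	U	Psi	Unknown	
18S	553	U	Psi	Unknown	
18S	554	U	Psi	Unknown	
18S	558	U	Psi	Unknown	
18S	566	U	Psi	Unknown	
18S	579	U	Psi	Unknown	
18S	608	U	Psi	Unknown	
18S	634	U	Psi	Unknown	
18S	664	U	Psi	Unknown	
18S	681	U	Psi	Unknown	
18S	697	U	Psi	Unknown	
18S	786	U	Psi	Unknown	
18S	849	U	Psi	Unknown	
18S	860	U	Psi	Unknown	
18S	892	U	Psi	Unknown	
18S	897	U	Psi	SNORA44	
18S	928	U	Psi	Unknown	
18S	1012	U	Psi	Unknown	
18S	1046	U	Psi	Unknown	
18S	1116	U	Psi	Unknown	
18S	1278	U	Psi	Unknown	
18S	1336	U	Psi	Unknown	
18S	1395	U	Psi	Unknown	
18S	1406	U	Psi	Unknown	
18S	1420	U	Psi	Unknown	
18S	1496	U	Psi	Unknown	
18S	1497	U	Psi	Unknown	
18S	1527	U	Psi	Unknown	
18S	1539	U	Psi	Unknown	
18S	1618	U	Psi	Unknown	
18S	1660	U	Psi	Unknown	
18S	1708	U	Psi	Unknown	
18S	1719	U	Psi	Unknown	
18S	1744	U	Psi	Unknown	
18S	1795	U	Psi	Unknown	
18S	1801	U	Psi	Unknown	
28S	94	U	Psi	Unknown	
28S	106	U	Psi	Unknown	
28S	146	U	Psi	Unknown	
28S	223	U	Psi	Unknown	
28S	391	U	Psi	Unknown	
28S	421	U	Psi	Unknown	
28S	526	U	Psi	Unknown	
28S	562	U	Psi	Unknown	
28S	698	U	Psi	Unknown	
28S	799	U	Psi	Unknown	
28S	871	U	Psi	Unknown	
28S	889	U	Psi	Unknown	
28S	897	U	Psi	Unknown	
28S	914	U	Psi	Unknown	
28S	1166	U	Psi	Unknown	
28S	1269	U	Psi	Unknown	
28S	1536	U	Psi	Unknown	
28S	1582	U	Psi	SNORA7A;SNORA7B	1569
28S	1779	U	Psi	SNORA47	1766
28S	1903	U	Psi	Unknown	
28S	2036	U	Psi	Unknown	
28S	2124	U	Psi	Unknown	
28S	2167	U	Psi	Unknown	
28S	2264	U	Psi	Unknown	
28S	2302	U	Psi	Unknown	
28S	2469	U	Psi	Unknown	
28S	2539	U	Psi	Unknown	
28S	2548	U	Psi	Unknown	
28S	2801	U	Psi	Unknown	
28S	2810	U	Psi	Unknown	
28S	2816	U	Psi	Unknown	
28S	2839	U	Psi	Unknown	2826
28S	2843	U	Psi	Unknown	2830
28S	3038	U	Psi	Unknown	
28S	3465	U	Psi	Unknown	
28S	3486	U	Psi	Unknown	
28S	3734	U	Psi	SNORA31	3713
28S	3776	U	Psi	Unknown	
28S	3822	U	Psi	SNORA54	3801
28S	3884	U	Psi	Unknown	
28S	3960	U	Psi	Unknown	
28S	4023	U	Psi	Unknown	
28S	4059	U	Psi	Unknown	
28S	4080	U	Psi	Unknown	
28S	4160	U	Psi	Unknown	
28S	4220	U	Psi	Unknown	
28S	4241	U	Psi	Unknown	
28S	4254	U	Psi	Unknown	
28S	4312	U	Psi	SNORA2A;SNORA2B;SNORA34	4282
28S	4329	U	Psi	Unknown	
28S	4341	U	Psi	Unknown	
28S	4381	U	Psi	Unknown	
28S	4411	U	Psi	Unknown	
28S	4420	U	Psi	SNORA63	4390
28S	4579	U	Psi	Unknown	4549
28S	4636	U	Psi	SNORA81	4606
28S	4673	U	Psi	SNORA30;SNORA37	4643
28S	4763	U	Psi	Unknown	
28S	4852	U	Psi	Unknown	
28S	4973	U	Psi	SNORA43	4938
28S	5001	U	Psi	SNORA22;SNORA33	4966
5.8S	55	U	Psi	Unknown	
5.8S	69	U	Psi	Unknown	
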