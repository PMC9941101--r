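molecule	position	residue	mod_type	guides	legacy_position
18S	174	C	Nm	SNORD45C	
18S	183	U	Nm	Unknown	
18S	264	U	Nm	Unknown	
18S	289	U	Nm	Unknown	
18S	337	C	Nm	Unknown	
18S	354	U	Nm	SNORD90	
18S	377	A	Nm	Unknown	
18S	385	U	Nm	Unknown	
18S	389	U	Nm	Unknown	
18S	425	U	Nm	Unknown	
18S	436	G	Nm	SNORD100	
18S	473	C	Nm	Unknown	
18S	510	G	Nm	Unknown	
18S	545	C	Nm	Unknown	
18S	569	U	Nm	Unknown	
18S	576	A	Nm	SNORD93	
18S	717	U	Nm	Unknown	
18S	754	A	Nm	Unknown	
18S	867	G	Nm	SNORD98	
18S	879	A	Nm	Unknown	
18S	925	G	Nm	Unknown	
18S	951	C	Nm	SNORD114-3	
18S	977	G	Nm	Unknown	
18S	979	C	Nm	Unknown	
18S	995	G	Nm	SNORD53	
18S	1000	C	Nm	SNORD44	
18S	1031	U	Nm	Unknown	
18S	1034	A	Nm	SNORD59A	
18S	1141	C	Nm	Unknown	
18S	1272	C	Nm	SNORD66	
18S	1325	A	Nm	Unknown	
18S	1362	C	Nm	Unknown	
18S	1365	G	Nm	Unknown	
18S	1391	C	Nm	Unknown	
18S	1440	C	Nm	SNORD125	
18S	1595	A	Nm	Unknown	
18S	1639	G	Nm	SNORD81	
18S	1690	A	Nm	Unknown	
18S	1696	G	Nm	Unknown	
18S	1757	A	Nm	Unknown	
18S	1830	A	Nm	Unknown	
28S	79	A	Nm	Unknown	
28S	205	C	Nm	Unknown	
28S	208	A	Nm	Unknown	
28S	273	C	Nm	Unknown	
28S	327	G	Nm	Unknown	
28S	347	C	Nm	Unknown	
28S	365	U	Nm	Unknown	
28S	424	C	Nm	Unknown	
28S	473	C	Nm	Unknown	
28S	499	G	Nm	Unknown	
28S	585	U	Nm	Unknown	
28S	593	C	Nm	Unknown	
28S	750	A	Nm	Unknown	
28S	856	A	Nm	Unknown	
28S	902	G	Nm	Unknown	
28S	1031	C	Nm	Unknown	
28S	1253	C	Nm	Unknown	
28S	1323	A	Nm	SNORD126	1310
28S	1359	C	Nm	Unknown	
28S	1384	G	Nm	Unknown	
28S	1400	A	Nm	Unknown	
28S	1881	C	Nm	SNORD48	1868
28S	2069	G	Nm	Unknown	
28S	2075	C	Nm	SNORD114-14	
28S	2217	A	Nm	Unknown	
28S	2315	A	Nm	Unknown	
28S	2326	C	Nm	Unknown	
28S	2328	G	Nm	Unknown	
28S	2341	U	Nm	Unknown	
28S	2401	A	Nm	SNORD68	2388
28S	2639	C	Nm	Unknown	
28S	2694	U	Nm	Unknown	
28S	2702	G	Nm	Unknown	
28S	2721	C	Nm	Unknown	
28S	2787	A	Nm	SNORD99	2774
28S	2861	C	Nm	SNORD50A;SNORD50B	2848
28S	2876	G	Nm	SNORD50A;SNORD50B	2863
28S	2937	C	Nm	Unknown	
28S	2951	G	Nm	Unknown	
28S	3021	G	Nm	Unknown	
28S	3033	A	Nm	Unknown	
28S	3156	A	Nm	Unknown	
28S	3170	C	Nm	Unknown	
28S	3256	A	Nm	Unknown	
28S	3397	G	Nm	Unknown	
28S	3454	G	Nm	Unknown	
28S	3593	U	Nm	Unknown	
28S	3698	C	Nm	Unknown	
28S	3712	G	Nm	Unknown	
28S	3718	G	Nm	Unknown	
28S	3749	C	Nm	Unknown	
28S	3757	A	Nm	Unknown	
28S	3770	C	Nm	Unknown	
28S	3812	A	Nm	Unknown	
28S	3867	A	Nm	SNORD92	3846
28S	3893	U	Nm	Unknown	
28S	3904	U	Nm	SNORD52	
28S	4042	G	Nm	SNORD102	4020
28S	4130	G	Nm	Unknown	
28S	4247	G	Nm	Unknown	
28S	4456	C	Nm	SNORD49A;SNORD49B	4426
28S	4676	A	Nm	Unknown	
28S	4682	A	Nm	Unknown	
28S	4769	A	Nm	Unknown	
28S	4780	G	Nm	Unknown	
28S	4820	C	Nm	Unknown	
28S	5008	A	Nm	Unknown	
5.8S	14	U	Nm	Unknown	
5.8S	75	G	Nm	Unknown	
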