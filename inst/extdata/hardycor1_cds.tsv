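start	stop	locus_tag	length_nt	strand	gene	product
138	791	HrrHc1_005	654	+		hypothetical protein
788	1012	HrrHc1_010	225	+		CxxC motif protein
1009	1323	HrrHc1_015	315	+		hypothetical protein
1320	1883	HrrHc1_020	564	+	dam	probable Dam methylase
1880	2260	HrrHc1_025	381	+		CxxC motif protein
2337	3560	HrrHc1_030	1224	+	terL	large subunit terminase TerL
3809	5407	HrrHc1_035	1599	+	por	portal protein Por
5412	7382	HrrHc1_040	1971	+	muf	SPP1 gp7 family protein MuF
7479	8501	HrrHc1_045	1023	+		hypothetical protein
8506	8820	HrrHc1_050	315	-		CxxC motif protein
8986	10470	HrrHc1_055	1485	+		hypothetical protein
10474	10911	HrrHc1_060	438	+		hypothetical protein
10913	11989	HrrHc1_065	1077	+	mcp	major capsid protein Mcp
12070	12501	HrrHc1_070	432	+		hypothetical protein
12505	12933	HrrHc1_075	429	+		DUF1073 domain protein
12935	13288	HrrHc1_080	354	+	nep1	neck protein Nep1
13285	13710	HrrHc1_085	426	+		hypothetical protein
13707	14201	HrrHc1_090	495	+		hypothetical protein
14337	15266	HrrHc1_095	930	-		hypothetical protein
15676	15879	HrrHc1_100	204	+		hypothetical protein
15883	17115	HrrHc1_105	1233	+		hypothetical protein
17143	17613	HrrHc1_110	471	+		hypothetical protein
17688	17894	HrrHc1_115	207	+		hypothetical protein
17894	20005	HrrHc1_120	2112	+	tmp	tape measure protein Tmp
20007	20552	HrrHc1_125	546	+		hypothetical protein
20554	21759	HrrHc1_130	1206	+		hypothetical protein
21756	22067	HrrHc1_135	312	+		hypothetical protein
22069	22527	HrrHc1_140	459	+		hypothetical protein
22599	24518	HrrHc1_145	1920	+		hypothetical protein
24574	24813	HrrHc1_150	240	+		hypothetical protein
24825	25175	HrrHc1_155	351	+		predicted membrane protein
25290	26255	HrrHc1_160	966	+		hypothetical protein
26324	26917	HrrHc1_165	594	+		hypothetical protein
27104	27502	HrrHc1_170	399	-		CxxC motif protein
27499	27936	HrrHc1_175	438	-	hjc	H-J resolvase Hjc
28034	28390	HrrHc1_180	357	-		hypothetical protein
28390	28674	HrrHc1_185	285	-		hypothetical protein
28671	29117	HrrHc1_190	447	-		hypothetical protein
29114	29314	HrrHc1_195	201	-		CxxC motif protein
29311	29610	HrrHc1_200	300	-		CxxC motif protein
29607	29867	HrrHc1_205	261	-		CxxC motif protein
29860	31395	HrrHc1_210	1536	-		nucleic acid binding domain protein
31392	32585	HrrHc1_215	1194	-		hypothetical protein
32774	32938	HrrHc1_220	165	-		CxxC motif protein
32935	33327	HrrHc1_225	393	-		CxxC motif protein
33324	35321	HrrHc1_230	1998	-		hypothetical protein
35523	37079	HrrHc1_235	1557	-		CxxC motif protein
37288	38694	HrrHc1_240	1407	-	aaa	AAA ATPase
38836	40968	HrrHc1_245	2133	-	vwa	vWA and MIDAS domain protein
41082	42461	HrrHc1_250	1380	-		hypothetical protein
42458	43084	HrrHc1_255	627	-		hypothetical protein
43162	43923	HrrHc1_260	762	+		hypothetical protein
44232	44936	HrrHc1_265	705	+		hypothetical protein
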