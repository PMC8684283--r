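chrom	start_mb	end_mb	total_delta	size_mb	positive_genes
3	58	59	1090.88	1	BCL10,C1orf52
5	43	44	1020.05	1	SYT10
6	2	4	2016.60	2	ANXA5,BBS7,EXOSC9
7	0	1	1034.72	1	STARD4
7	29	30	1052.05	1	ACOT12,ANKRD34B,CKMT2,FAM151B,RASGRF2,SSBP2
10	86	87	1094.05	1	CEP128
11	11	13	2084.10	2	CYP26B1,DYSF,EMX1,EXOC6B,SPR
11	14	30	17237.41	16	BIRC6,CRIM1,DPY30,MEMO1,NLRC4,SLC30A6,SPAST,TTC27,YIPF4
11	95	96	1144.55	1	MAPKAP1,PBX3
12	11	12	1076.72	1	NAA16,VWA8
13	0	21	2459.58	21	AHCY,DYNLRB1,MAFB,MAP1LC3A,PIGU,TOP1
14	67	68	1117.55	1	SDC2
14	81	83	2138.93	2	SNTB1
16	59	66	7608.05	7	ZNF648
17	0	5	5367.15	5	TTC28
23	32	33	1068.35	1	ABT1,HFE,PRSS16,SLC17A2,TRIM38,ZNF184,ZNF391
25	12	23	11676.41	11	AQP8,LCMT1,SCNN1G,USP31
26	13	14	964.55	1	RAB11FIP2
26	24	34	10574.31	10	ABCC2,CHUK,COX15,CPN1,CRTAC1,CUTC,DNMBP,ENTPD7,ERLIN1,SFRP5,SORCS1,ZFYVE27
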