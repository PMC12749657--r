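patient	sex	age	smoking	tumor_type	cyp2a6_cnv
1	F	79	never	LUAD	0.2
2	M	86	heavy	LUAD	0.0
3	F	81	heavy	LUAD	0.0
4	M	73	heavy	LUAD	0.0
5	F	68	heavy	LUAD	0.0
6	F	78	never	LUAD	1.1
7	M	63	heavy	LUAD	1.1
8	F	58	never	LUAD	2.0
9	M	74	heavy	LUAD	2.0
10	M	75	heavy	LUSC	3.0
11	F	79	heavy	LUSC	3.0
12	M	81	heavy	LUSC	2.9
13	M	79	heavy	LUAD	1.7
14	M	75	heavy	LUAD	1.7
15	F	74	never	READ	3.0
16	M	71	heavy	READ	2.9
17	F	68	never	COAD	1.9
18	M	50	heavy	GIST	1.9
19	M	75	light	ESCC	1.4
20	M	48	heavy	CCRCC	1.4
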