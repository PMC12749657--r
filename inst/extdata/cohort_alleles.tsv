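patient	tumor_type	amplicon	allele1	allele2	genome_class
1	LUAD	(c)	IGR::IGR	IGR::IGR	deletion
2	LUAD	(c)	3'UTR::3'UTR	IGR::IGR	deletion
3	LUAD	(c)	3'UTR::3'UTR	3'UTR::3'UTR	deletion
4	LUAD	(c)	3'UTR::3'UTR	3'UTR::3'UTR	deletion
5	LUAD	(c)	3'UTR::3'UTR	3'UTR::3'UTR	deletion
6	LUAD	(c)	3'UTR::3'UTR	Wild-type::Wild-type	retained
7	LUAD	(c)	3'UTR::3'UTR	Wild-type::Wild-type	retained
8	LUAD	N.A	Wild-type::Wild-type	Wild-type::Wild-type	retained
9	LUAD	N.A	Wild-type::Wild-type	Wild-type::Wild-type	retained
10	LUSC	N.A	Wild-type::Dup	Wild-type::Wild-type	retained
11	LUSC	N.A	Wild-type::Dup	Wild-type::Wild-type	retained
12	LUSC	N.A	Wild-type::Dup	Wild-type::Wild-type	retained
13	LUAD	(b)/(c)	int3::int3	Wild-type::Wild-type	retained
14	LUAD	(a)/(c)	int1::int1	Wild-type::Wild-type	retained
15	READ	N.A	Wild-type::Dup	Wild-type::Wild-type	retained
16	READ	N.A	Wild-type::Dup	Wild-type::Wild-type	retained
17	COAD	(a)/(c)	int1::int1	3'UTR::3'UTR	deletion
18	GIST	(a)/(c)	int1::int1	3'UTR::3'UTR	deletion
19	ESCC	(c)/(d)	int5::int5	3'UTR::3'UTR	deletion
20	CCRCC	(c)/(d)	int5::int5	3'UTR::3'UTR	deletion
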