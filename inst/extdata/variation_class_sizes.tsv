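method	type	n	min_size	median_size	max_size	total_bases
consensus_snp	SNP	2859650	1	1	1	2859650
intersect_indel	indel	197895	1	1	12	349248
matepair_sv	sv	8596	42	122	127536	6286578
splitread_sv	sv	1416	13	22	855018	1147264
multi_platform_cnv	CNV	46	3170	25812	595739	3889717
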