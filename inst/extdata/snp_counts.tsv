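metric	value
union_snp_sites	6239482
four_caller_intersection	2859650
single_caller_only	1774648
coding_snps	27722
total_intra_read_indels	197895
coding_indels	417
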