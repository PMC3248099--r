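platform	n_cnv	total_bp
cgh	196	6110000
snp_array	30	2570000
readdepth	520	3630000
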