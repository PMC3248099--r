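class	before	after
inversion	412	297
intra_translocation	120	86
inter_translocation	18	13
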