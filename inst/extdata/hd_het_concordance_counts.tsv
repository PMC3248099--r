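pipeline	consistent	het_to_hom	as_indel	inconsistent
bwa	167758	10590	30	477
clc	175322	9589	46	438
giga	158564	4467	196	0
smalt	151792	9097	31	401
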