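pipeline	consistent	hom_to_het	as_indel	inconsistent
bwa	253102	247	107	16
clc	254195	848	101	28
giga	236261	3522	1860	20
smalt	247805	272	96	19
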