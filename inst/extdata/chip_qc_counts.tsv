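chip	effective	mapped	het	hom
HD	770343	756243	207670	547727
SNP50	52345	42603	11569	31018
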