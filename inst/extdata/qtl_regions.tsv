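trait	region	chrom	span_cM	phys_start	phys_end
anther_color	qAC	Chr6	22.280	33627819	34877940
hull_color	qHC	Chr1	21.144	1	6229734
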