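trait	qtl	chrom	peak_cM	marker_interval	map_lo_cM	map_hi_cM	phys_start	phys_end	lod	additive_effect	r2
anther_color	qAC1	Chr6	236.21	Chr6_bin141-Chr6_bin142	232.198	238.452	34039911	34200621	169.01	0.47	0.89
anther_color	qAC2	Chr6	248.86	Chr6_bin152-Chr6_bin153	248.847	250.449	34820013	34877940	108.63	0.43	0.72
hull_color	qHC1	Chr1	7.51	Chr1_bin4-Chr1_bin5	5.497	8.528	2615096	5411711	152.64	0.48	0.90
hull_color	qHC2	Chr1	10.27	Chr1_bin7-Chr1_bin8	10.258	11.110	5485413	5698001	143.69	0.45	0.82
hull_color	qHC3	Chr1	12.93	Chr1_bin10-Chr1_bin11	12.918	14.584	5745038	5989490	133.79	0.45	0.80
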