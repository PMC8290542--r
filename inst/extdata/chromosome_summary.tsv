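chromosome	length_bp	bin_number	linkage_cM	gv_number	gv_density_per_50kb
Chr1	42145699	76	166.375	467	0.55
Chr2	49200776	44	50.75	1402	1.42
Chr3	50652576	242	272.681	7983	7.88
Chr4	40408058	56	582.516	403	0.50
Chr5	47253416	165	246.408	3687	3.90
Chr6	36015257	170	272.712	2983	4.14
Chr7	35964515	69	116.238	1225	1.70
Chr8	40690061	269	170.248	15315	18.82
Chr9	58970518	213	318.173	12558	10.65
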