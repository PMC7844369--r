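locus	gene	mean_case	sd_case	n_case	mean_control	sd_control	n_control	p_printed
cg23371584	BTG2	10.598	4.396	30	8.063	5.085	30	0.043
cg15971518	PRG2	24.633	14.445	30	35.263	20.422	30	0.023
cg04481923	VTRNA2-1	28.401	14.699	30	35.421	12.142	30	0.048
cg22507406	PER3	71.532	2.474	30	73.576	3.500	30	0.011
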