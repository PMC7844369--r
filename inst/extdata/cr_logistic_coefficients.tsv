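term	estimate	std_error	wald	p_value	odds_ratio
albumin	-0.205	0.092	5.028	0.025	0.814
uric_acid	0.008	0.003	6.751	0.009	1.008
constant	5.499	3.402	2.612	0.106	244.485
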