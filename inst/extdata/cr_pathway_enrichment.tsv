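set_id	name	k	list_fraction_pct	p	fdr	fold
hsa04713	Circadian entrainment	36	3.0848	3.82e-6	0.0010	2.0682
hsa04020	Calcium signaling pathway	53	4.5416	1.40e-4	0.0150	1.5813
hsa04911	Insulin secretion	30	2.5707	1.82e-4	0.0150	1.8838
hsa04728	Dopaminergic synapse	40	3.4276	2.35e-4	0.0150	1.6876
hsa04270	Vascular smooth muscle contraction	37	3.1705	3.77e-4	0.0193	1.6933
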