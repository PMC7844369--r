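gene	mean_case	sd_case	n_case	mean_control	sd_control	n_control	p_printed
BTG2	0.267	0.031	30	0.293	0.044	30	0.016
PRG2	0.423	0.163	30	0.336	0.096	30	0.002
VTRNA2-1	1.167	0.285	30	1.007	0.213	30	0.048
PER3	0.397	0.056	30	0.308	0.072	30	0.001
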