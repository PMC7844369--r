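variable	g1_yes	g1_no	g2_yes	g2_no	chi2_printed	p_printed
male_gender	8	22	7	23	0.089	0.766
alcohol_abuse	24	6	22	8	0.373	0.542
hypertension	10	20	10	20	0.000	1.000
diabetes	26	4	21	9	2.455	0.117
dyslipidemia	16	14	18	12	0.271	0.602
current_smoking	23	7	18	12	1.926	0.165
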