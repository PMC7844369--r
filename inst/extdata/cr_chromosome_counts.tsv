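chr	n_hypo	n_hyper
1	575	84
2	475	75
3	341	66
4	268	44
5	349	61
6	345	64
7	366	44
8	270	36
9	221	20
10	308	52
11	378	63
12	291	66
13	152	18
14	218	42
15	163	37
16	288	36
17	280	57
18	112	16
19	264	47
20	200	31
21	88	10
22	167	10
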