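sex	adhd	n	any_ed	an	oed	bn
all	1	108443	2887	998	2586	741
all	0	3441675	30030	14217	22962	7090
F	1	38339	2588	916	2323	709
F	0	1687972	28260	13425	21659	6938
M	1	70104	299	82	263	32
M	0	1753703	1770	792	1303	152
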