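trait	class	both_affected	both_unaffected	discordant	with_both_disorders	cross_concordant
adhd	full_sister	787	322529	11117	NA	NA
adhd	maternal_half_sister	292	52031	4713	NA	NA
an	full_sister	107	328436	5890	343	150
an	maternal_half_sister	5	56103	928	99	44
oed	full_sister	250	324912	9271	853	331
oed	maternal_half_sister	19	55133	1884	286	107
bn	full_sister	34	331325	3074	273	87
bn	maternal_half_sister	4	56461	571	79	37
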