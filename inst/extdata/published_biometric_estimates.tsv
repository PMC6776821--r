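quantity	trait	estimate	lo	hi
a2	adhd	0.82	0.78	0.85
a2	an	0.42	0.35	0.49
a2	oed	0.44	0.39	0.49
a2	bn	0.40	0.35	0.51
coher_a	an	0.42	0.16	0.69
coher_a	oed	0.73	0.60	0.85
coher_a	bn	0.58	0.35	0.81
rg	an	0.14	0.05	0.22
rg	oed	0.37	0.31	0.42
rg	bn	0.28	0.20	0.39
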