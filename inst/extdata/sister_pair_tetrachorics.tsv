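trait	class	r_within	r_within_lo	r_within_hi	r_phen	r_phen_lo	r_phen_hi	r_cross	r_cross_lo	r_cross_hi
adhd	full_sister	0.41	0.39	0.42	NA	NA	NA	NA	NA	NA
adhd	maternal_half_sister	0.22	0.19	0.25	NA	NA	NA	NA	NA	NA
an	full_sister	0.21	0.18	0.25	0.19	0.17	0.21	0.04	0.04	0.04
an	maternal_half_sister	0.03	-0.10	0.15	0.17	0.13	0.21	0.004	-0.05	0.06
oed	full_sister	0.23	0.20	0.25	0.31	0.30	0.33	0.11	0.09	0.13
oed	maternal_half_sister	0.02	-0.05	0.10	0.28	0.25	0.31	0.04	0.01	0.08
bn	full_sister	0.20	0.16	0.24	0.28	0.26	0.30	0.07	0.07	0.07
bn	maternal_half_sister	0.13	-0.02	0.27	0.23	0.19	0.28	0.07	0.01	0.13
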