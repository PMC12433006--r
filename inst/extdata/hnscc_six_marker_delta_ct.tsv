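sample_id	group	marker	delta_ct
T-0025-N	control	FLI1	20.82
T-0025-N	control	LHX8	8.01
T-0025-N	control	USP44	9.29
T-0025-N	control	KCNB1	12.87
T-0025-N	control	ZNF529	20.82
T-0025-N	control	URAD	4.71
T-0045-N	control	FLI1	19.03
T-0045-N	control	LHX8	16.40
T-0045-N	control	USP44	9.74
T-0045-N	control	KCNB1	19.03
T-0045-N	control	ZNF529	13.85
T-0045-N	control	URAD	8.08
T-0099-N	control	FLI1	11.93
T-0099-N	control	LHX8	7.13
T-0099-N	control	USP44	8.76
T-0099-N	control	KCNB1	9.34
T-0099-N	control	ZNF529	9.92
T-0099-N	control	URAD	9.45
T-0044-C	tumor	FLI1	0.73
T-0044-C	tumor	LHX8	0.46
T-0044-C	tumor	USP44	1.24
T-0044-C	tumor	KCNB1	0.18
T-0044-C	tumor	ZNF529	3.41
T-0044-C	tumor	URAD	1.97
T-0085-C	tumor	FLI1	2.91
T-0085-C	tumor	LHX8	1.56
T-0085-C	tumor	USP44	2.42
T-0085-C	tumor	KCNB1	2.58
T-0085-C	tumor	ZNF529	4.98
T-0085-C	tumor	URAD	1.75
T-0126-C	tumor	FLI1	7.16
T-0126-C	tumor	LHX8	1.83
T-0126-C	tumor	USP44	7.14
T-0126-C	tumor	KCNB1	19.80
T-0126-C	tumor	ZNF529	4.02
T-0126-C	tumor	URAD	2.09
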