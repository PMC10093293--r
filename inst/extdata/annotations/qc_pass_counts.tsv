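cohort	tissue_type	passed	total	printed_pct
validation	breast_tumor	20	23	86
validation	breast_adjacent_normal	6	23	26
validation	mastectomy_normal	12	32	37.5
validation	ovarian_normal	33	41	80.5
validation	salpingian_normal	34	42	81
research	breast_tumor	90	95	94.7
research	breast_normal	38	95	40
overall	all	236	354	66.5
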