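cohort	cluster	n	grs_mean	grs_sd	female_n
cohort1	A	142	14.15	1.31	93
cohort1	B	120	12.52	2.16	53
cohort1	C	111	12.33	1.95	60
cohort1	D	102	10.67	1.44	57
cohort2	A	28	14.39	1.17	17
cohort2	B	63	14.19	1.40	41
cohort2	C	50	12.74	1.58	18
cohort2	D	28	11.14	1.65	20
cohort2	E	68	10.88	1.38	44
cohort3	A	87	14.83	1.08	46
cohort3	B	89	12.78	1.83	44
cohort3	C	73	12.01	1.88	44
cohort3	D	85	11.46	1.33	50
cohort3	E	112	11.04	1.74	79
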