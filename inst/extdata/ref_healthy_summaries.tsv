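cohort	n	grs_mean	grs_sd
cohort1	565	12.71	2.10
cohort2	965	12.50	2.08
cohort3	673	12.46	2.15
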