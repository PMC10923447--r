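rsid	chrom	pos	gene	risk_allele	other_allele	consequence	maf	imputation_r2	genotyped
rs3795958	2	26624210	CCDC164	G	A	missense	0.22	NA	1
rs12623642	2	26631870	CCDC164	T	C	missense	0.35	NA	1
rs2277046	5	13717471	DNAH5	G	T	missense	0.49	NA	1
rs10513155	5	13810544	DNAH5	T	C	missense	0.18	NA	1
rs1530498	5	13929010	DNAH5	G	A	utr3	0.27	NA	1
rs1530496	5	13931340	DNAH5	A	G	utr3	0.31	NA	1
rs2285943	7	21522994	DNAH11	T	G	missense	0.41	NA	1
rs10224537	7	21610212	DNAH11	G	T	missense	0.15	NA	1
rs2214326	7	21701350	DNAH11	A	G	missense	0.24	NA	1
rs7971	7	21781466	DNAH11	G	C	missense	0.38	NA	1
rs10250905	7	37892165	TXNDC3	C	T	missense	0.29	NA	1
rs600753	15	55712607	DYX1C1	G	A	missense	0.33	NA	1
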