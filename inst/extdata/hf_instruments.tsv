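rsid	chrom	pos	gene	effect_allele	other_allele	eaf	beta	se	pval	n	f_reported
rs1510226	6	160816409	SLC22A3	C	T	0.01	0.162	0.029	1.27e-08	977323	32.31
rs17617337	10	121426884	BAG3	T	C	0.22	-0.056	0.010	3.65e-09	977323	34.87
rs4135240	6	36647680	CDKN1A	C	T	0.34	-0.049	0.008	6.84e-09	977323	33.47
rs55730499	6	161005610	LPA	T	C	0.07	0.106	0.016	1.83e-11	977323	45.41
rs600038	9	136151806	ABO, SURF1	C	T	0.21	0.057	0.010	3.68e-09	977323	35.13
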