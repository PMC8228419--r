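rsid	effect_allele	other_allele	eaf	beta	se	pvalue	n	locus	trait	unit
rs964184	C	G	0.14	0.072	0.01052	7.7e-12	7781	11q23.3	alpha-tocopherol	log mg/L
rs2108622	T	C	0.29	0.048	0.00748	1.39e-10	7781	19pter-p13.11	alpha-tocopherol	log mg/L
rs11057830	A	G	0.85	0.042	0.00729	8.35e-09	7781	12q24.31	alpha-tocopherol	log mg/L
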