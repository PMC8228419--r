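rsid	effect_allele	other_allele	eaf	beta	se	pvalue	n	trait	unit
rs964184	C	G	0.135	0.0216	0.0047	4.31e-06	426824	eBMD	g/cm2
rs2108622	T	C	0.3	0.01536	0.0032	1.59e-06	426824	eBMD	g/cm2
rs11057830	A	G	0.85	0.0062793	0.0041	0.126	426824	eBMD	g/cm2
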