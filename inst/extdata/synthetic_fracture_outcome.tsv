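rsid	effect_allele	other_allele	eaf	beta	se	pvalue	n	trait	unit
rs964184	C	G	0.135	-0.0108	0.0152	0.477	426795	fracture	log-odds
rs2108622	T	C	0.3	-0.0024	0.0126	0.849	426795	fracture	log-odds
rs11057830	A	G	0.85	-0.0040862	0.0137	0.766	426795	fracture	log-odds
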