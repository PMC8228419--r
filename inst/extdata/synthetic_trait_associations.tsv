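rsid	trait	pvalue
rs964184	phylloquinone	6e-08
rs2108622	phylloquinone	8.8e-07
rs964184	triglycerides	1e-20
rs2108622	height	0.02
rs11057830	HDL cholesterol	3e-09
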