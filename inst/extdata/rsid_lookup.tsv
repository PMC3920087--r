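rsid	level	hgvs
rs1000	dna	c.35G>A
rs1000	protein	G12D
rs1042522	dna	c.215C>G
rs1042522	protein	P72R
rs121913529	dna	c.35G>T
rs121913529	protein	G12V
rs28934578	dna	c.524G>A
rs28934578	protein	R175H
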