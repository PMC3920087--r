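heading	tree_codes
Computational biology	H01.158.273.180
Genetic techniques	E05.393
Genome	G05.360.340
Molecular sequence data	L01.453.245.667
Proteome	D12.776.817
Proteomics	H01.181.122.738
Genomics	H01.158.273.180.350
Sequence analysis, DNA	E05.393.760.700
High-throughput nucleotide sequencing	E05.393.760.710
Genome-wide association study	E05.393.365
Gene expression profiling	E05.393.332
DNA mutational analysis	E05.393.225
Human genome	G05.360.340.358
Humans	B01.050.150.900
Neoplasms	C04.588
Colorectal neoplasms	C04.588.274
Mutation	G05.365.590
Germ-line mutation	G05.365.590.390
Middle aged	M01.060.116.630
Case-control studies	E05.318.760.500
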