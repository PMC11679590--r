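name	sequence	role	target_species
LCO 1490	GGTCAACAAATCATAAAGATATTGG	barcoding
HCO 2198	TAAACTTCAGGGTGACCAAAAAATCA	barcoding
MMRC_1955	CAGATCTACCACCATGAGCAATA	common_reverse
MMRC_1964	GGATTTGGTAATTGACTTGTACCTCTT	species_forward	C. includens
MMRC_1988	TCCTGGATCTTTAATTGGAGAT	species_forward	R. nu
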