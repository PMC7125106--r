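target	label	numerator	denominator
t1	genes_ge_100aa_of_total	20299	22483
t2	orfan_of_total	7217	22483
t3	bacteria_of_total	2295	22483
t4	eukaryote_of_total	12567	22483
t5	amoebozoa_of_total	4457	22483
t6	proteobacteria_of_bacterial	811	2295
t7	cpr_of_bacterial	30	2295
t8	virus_of_total	188	22483
t10	archaea_of_total	139	22483
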