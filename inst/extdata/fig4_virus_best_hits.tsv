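organism	n_genes
Bodo saltans virus	69
Klosneuvirus KNV1	16
Catovirus CTV1	10
Hokovirus HKV1	3
Indivirus ILV1	3
Tupanvirus deep ocean	16
Tupanvirus soda lake	4
Orpheovirus IHUMI-LCC2	34
Faustovirus	16
Kaumoebavirus	4
Cedratvirus	2
Pandoravirus inopinatum	1
Acanthocystis turfacea Chlorella virus	4
Phaeocystis globosa virus	1
Ralstonia phage phiRSL1	2
Synechococcus phage S-SKS1	1
Canarypox virus	1
African swine fever virus	1
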