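marker	subgroup	is_cpr	is_giant_virus
Amoebozoa	Amoebozoa	FALSE	FALSE
Proteobacteria	Proteobacteria	FALSE	FALSE
Bacteroidetes	Bacteroidetes	FALSE	FALSE
Cyanobacteria	Cyanobacteria	FALSE	FALSE
Actinobacteria	Actinobacteria	FALSE	FALSE
Firmicutes	Firmicutes	FALSE	FALSE
Euryarchaeota	Euryarchaeota	FALSE	FALSE
Thaumarchaeota	Thaumarchaeota	FALSE	FALSE
Parcubacteria	Parcubacteria	TRUE	FALSE
Microgenomates	Microgenomates	TRUE	FALSE
Peregrinibacteria	Peregrinibacteria	TRUE	FALSE
Doudnabacteria	Doudnabacteria	TRUE	FALSE
CPR2	CPR2	TRUE	FALSE
Klosneuvirinae	Klosneuvirinae	FALSE	TRUE
Tupanvirus	Tupanvirus	FALSE	TRUE
Orpheovirus	Orpheovirus	FALSE	TRUE
Faustovirus	Faustovirus	FALSE	TRUE
Kaumoebavirus	Kaumoebavirus	FALSE	TRUE
Cedratvirus	Cedratvirus	FALSE	TRUE
Pandoravirus	Pandoravirus	FALSE	TRUE
Phycodnaviridae	Phycodnaviridae	FALSE	TRUE
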