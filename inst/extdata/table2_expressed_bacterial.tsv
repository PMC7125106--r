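gene_id	best_hit	function	organism	read_count
g6416	WP_014678436.1	Tandem-95 repeat protein	Solitalea canadensis	349
g2762	ANE82214.1	Hypothetical protein A7U43_25800	Mycobacterium sp. YC-RL4	147
g4799	EQB29884.1	Arylsulfatase regulatory protein	Sphingobium ummariense RL-3	45
g11285	WP_054281538.1	NADPH dehydrogenase NamA	Chitinophagaceae bacterium PMP191F	37
g4808	ACF68028.1	Transposase	Salmonella enterica subsp. enterica serovar Heidelberg str. SL476	31
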