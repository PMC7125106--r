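gene_id	best_hit	function	organism
g4093	YP_009449258.1	Domain of unknown function (DUF4114)	Orpheovirus IHUMI-LCC2
g4206	YP_009449258.1	Domain of unknown function (DUF4114)	Orpheovirus IHUMI-LCC2
g10030	YP_009449258.1	Domain of unknown function (DUF4114)	Orpheovirus IHUMI-LCC2
g12378	YP_009448979.1	Cytochrome P450-like protein E-class	Orpheovirus IHUMI-LCC2
g13490	YP_009449258.1	Domain of unknown function (DUF4114)	Orpheovirus IHUMI-LCC2
g13679	YP_009449258.1	Domain of unknown function (DUF4114)	Orpheovirus IHUMI-LCC2
g14004	YP_009448979.1	Cytochrome P450-like protein E-class	Orpheovirus IHUMI-LCC2
g15726	YP_009352567.1	Peroxinectin	Kaumoebavirus
g18288	YP_009449258.1	Domain of unknown function (DUF4114)	Orpheovirus IHUMI-LCC2
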