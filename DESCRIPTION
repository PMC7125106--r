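Package: lstscreen
Title: Lateral Sequence Transfer Screening for Amoebal Draft Genomes
Version: 0.1.0
Authors@R:
    person("LST", "Screen Developers", email = "lstscreen@example.org",
           role = c("aut", "cre"))
Description: Screens a draft eukaryotic genome for candidate lateral
    sequence transfers from best-hit taxonomic profiling of predicted
    genes. Parses tabular protein homology hits, filters by e-value,
    selects best hits with deterministic tie-breaking, classifies donors
    against a taxonomy (superkingdoms, bacterial phyla, Candidate Phyla
    Radiation groups, giant-virus lineages), excludes suspected
    bacterial contaminant scaffolds, attaches RNA-seq expression
    support, contrasts intron densities by donor class, tests
    phylogenetic congruence with neighbor-joining bootstrap trees, and
    exports genome-mosaicism ("rhizome") link files together with
    summary reports. Ships a synthetic-data generator with planted
    ground truth so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
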