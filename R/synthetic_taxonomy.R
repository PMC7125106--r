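#' Synthetic reference taxonomy
#'
#' A small, fixed, code-built taxonomy used by the simulator and by the
#' bundled worked-example fixtures. It is a SYNTHETIC stand-in for the
#' reference taxonomy of a public protein database: organism names are real
#' (so the donor-group scheme is exercised on the names the field uses) but
#' the taxon ids are package-local and carry no meaning outside it.
#'
#' @return A `taxonomy_tree`.
#' @export
synthetic_taxonomy <- function() {
  n <- function(taxid, parent, rank, name)
    data.frame(taxid = taxid, parent = parent, rank = rank, name = name,
               stringsAsFactors = FALSE)
  nodes <- rbind(
    n(1L, 1L, "no_rank", "root"),
    n(2L, 1L, "superkingdom", "Eukaryota"),
    n(3L, 1L, "superkingdom", "Bacteria"),
    n(4L, 1L, "superkingdom", "Archaea"),
    n(5L, 1L, "superkingdom", "Viruses"),
    n(6L, 1L, "no_rank", "environmental samples"),
    n(7L, 6L, "species", "uncultured organism"),
    # Eukaryota
    n(10L, 2L, "phylum", "Amoebozoa"),
    n(11L, 10L, "genus", "Vermamoeba"),
    n(12L, 11L, "species", "Vermamoeba vermiformis"),
    n(13L, 10L, "genus", "Acanthamoeba"),
    n(14L, 13L, "species", "Acanthamoeba castellanii"),
    n(15L, 10L, "species", "Dictyostelium discoideum"),
    n(16L, 2L, "no_rank", "Opisthokonta"),
    n(17L, 16L, "species", "Homo sapiens"),
    n(18L, 16L, "species", "Saccharomyces cerevisiae"),
    n(19L, 2L, "no_rank", "Viridiplantae"),
    n(20L, 19L, "species", "Arabidopsis thaliana"),
    n(21L, 2L, "no_rank", "Discoba"),
    n(22L, 21L, "species", "Naegleria gruberi"),
    n(23L, 21L, "species", "Bodo saltans"),
    # Bacteria
    n(30L, 3L, "phylum", "Proteobacteria"),
    n(31L, 30L, "species", "Escherichia coli"),
    n(32L, 30L, "species", "Legionella pneumophila"),
    n(33L, 30L, "genus", "Sphingobium"),
    n(34L, 33L, "species", "Sphingobium ummariense RL-3"),
    n(35L, 30L, "species",
      "Salmonella enterica subsp. enterica serovar Heidelberg str. SL476"),
    n(36L, 3L, "phylum", "Bacteroidetes"),
    n(37L, 36L, "species", "Solitalea canadensis"),
    n(38L, 36L, "species", "Chitinophagaceae bacterium PMP191F"),
    n(39L, 3L, "phylum", "Cyanobacteria"),
    n(40L, 39L, "species", "Synechococcus elongatus"),
    n(41L, 3L, "phylum", "Actinobacteria"),
    n(42L, 41L, "species", "Mycobacterium sp. YC-RL4"),
    n(43L, 3L, "phylum", "Firmicutes"),
    n(44L, 43L, "species", "Bacillus subtilis"),
    # Candidate Phyla Radiation groups
    n(45L, 3L, "phylum", "Parcubacteria"),
    n(46L, 45L, "species", "Parcubacteria group bacterium GW2011"),
    n(47L, 3L, "phylum", "Microgenomates"),
    n(48L, 47L, "species", "Microgenomates group bacterium GW2011"),
    n(49L, 3L, "phylum", "Peregrinibacteria"),
    n(50L, 49L, "species", "Peregrinibacteria bacterium GW2011"),
    n(51L, 3L, "phylum", "Doudnabacteria"),
    n(52L, 51L, "species", "Doudnabacteria bacterium SM23"),
    n(53L, 3L, "phylum", "CPR2"),
    n(54L, 53L, "species", "CPR2 bacterium GW2011"),
    # Archaea
    n(60L, 4L, "phylum", "Euryarchaeota"),
    n(61L, 60L, "species", "Methanococcus maripaludis"),
    n(62L, 4L, "phylum", "Thaumarchaeota"),
    n(63L, 62L, "species", "Nitrososphaera viennensis"),
    # Viruses
    n(70L, 5L, "order", "Megavirales"),
    n(71L, 70L, "family", "Mimiviridae"),
    n(72L, 71L, "no_rank", "Klosneuvirinae"),
    n(73L, 72L, "species", "Bodo saltans virus"),
    n(74L, 72L, "species", "Klosneuvirus KNV1"),
    n(75L, 72L, "species", "Catovirus CTV1"),
    n(76L, 72L, "species", "Hokovirus HKV1"),
    n(77L, 72L, "species", "Indivirus ILV1"),
    n(78L, 71L, "genus", "Tupanvirus"),
    n(79L, 78L, "species", "Tupanvirus deep ocean"),
    n(80L, 78L, "species", "Tupanvirus soda lake"),
    n(81L, 70L, "genus", "Orpheovirus"),
    n(82L, 81L, "species", "Orpheovirus IHUMI-LCC2"),
    n(83L, 70L, "species", "Faustovirus"),
    n(84L, 70L, "species", "Kaumoebavirus"),
    n(85L, 70L, "species", "Cedratvirus"),
    n(86L, 70L, "genus", "Pandoravirus"),
    n(87L, 86L, "species", "Pandoravirus inopinatum"),
    n(88L, 5L, "family", "Phycodnaviridae"),
    n(89L, 88L, "species", "Acanthocystis turfacea Chlorella virus"),
    n(90L, 88L, "species", "Phaeocystis globosa virus"),
    n(91L, 5L, "order", "Caudovirales"),
    n(92L, 91L, "species", "Ralstonia phage phiRSL1"),
    n(93L, 91L, "species", "Synechococcus phage S-SKS1"),
    n(94L, 5L, "family", "Poxviridae"),
    n(95L, 94L, "species", "Canarypox virus"),
    n(96L, 5L, "family", "Asfarviridae"),
    n(97L, 96L, "species", "African swine fever virus")
  )
  tf <- tempfile(); nf <- tempfile()
  on.exit(unlink(c(tf, nf)))
  utils::write.table(nodes[, c("taxid", "parent", "rank")], tf, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(nodes[, c("taxid", "name")], nf, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  load_taxonomy(tf, nf)
}

# species-level donor taxid pools by simulated origin class; "self" is the
# query organism excluded from every pool
synthetic_donor_pools <- function() {
  list(self = 12L,
       eukaryote = c(17L, 18L, 20L, 22L, 23L),
       amoebozoa = c(14L, 15L),
       bacteria = c(31L, 32L, 34L, 35L, 37L, 38L, 40L, 42L, 44L),
       cpr = c(46L, 48L, 50L, 52L, 54L),
       archaea = c(61L, 63L),
       giant_virus = c(73L, 74L, 75L, 76L, 77L, 79L, 80L, 82L, 83L, 84L,
                       85L, 87L, 89L, 90L),
       other_virus = c(92L, 93L, 95L, 97L),
       unclassified = 7L)
}
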