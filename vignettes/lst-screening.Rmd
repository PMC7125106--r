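---
title: "Screening a draft amoebal genome for lateral sequence transfers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening a draft amoebal genome for lateral sequence transfers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening model

Free-living amoebae such as *Vermamoeba vermiformis* graze on bacteria and
host giant viruses; this shared (sympatric) intracellular lifestyle promotes
lateral sequence transfer (LST) between the amoeba and its
amoeba-resisting microorganisms. `lstscreen` implements the standard
best-hit screening pipeline for such a draft genome:

1. every predicted protein is searched against a reference protein
   database (outside this package); the resulting tabular hits, extended
   with subject taxon ids, are the input;
2. hits are filtered at an e-value threshold (default `1e-3`, boundary
   inclusive) and self-taxon hits are removed;
3. each gene gets its **best hit** — the record maximising bit score, ties
   broken by smaller e-value and then lexicographic subject id, so the
   choice is deterministic under permutation;
4. genes without surviving hits are **ORFans**; all others inherit the
   donor group of their best hit's taxonomic lineage (superkingdom;
   Amoebozoa; bacterial phylum; Candidate Phyla Radiation group;
   giant-virus lineage);
5. scaffolds whose genes are *all* assigned, *all* bacterial and *all*
   matching the same bacterium are excluded as suspected contaminants
   before any tally;
6. RNA-seq read counts call a gene transcribed at `>= 5` reads;
7. donor tallies, intron-density contrasts, NJ-bootstrap congruence tests
   and Circos-style rhizome link files summarise the evidence.

The screen is intentionally a *best-hit* classifier, not a
lowest-common-ancestor algorithm: the claim being screened for is "this
gene's closest relative is non-eukaryotic", and the per-organism report
(which bacterium? which giant virus?) requires the hit itself.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| `max_evalue` | `1e-3` | conventional protein-search threshold; the boundary is **inclusive** because "threshold of x" in common search tools retains `e = x` |
| `self_taxids` | none (pipeline passes the query species) | once the genome is deposited, every gene's best hit is itself |
| `min_reads` | 5 | transcription call, inclusive (`>= 5 reads`) |
| contaminant `rank` | `species` | "same bacteria" is organism-level wording; species is the coarsest rank that still separates the reported donor organisms |
| contaminant `min_genes` | 1 | literal reading of "totality": a single-gene bacterial scaffold satisfies it; raise to 2+ to audit |
| `min_aa` | 100 | protein-length filter, inclusive; the 300-bp variant is the same filter in nucleotide units |
| bootstrap `n_reps` | 100 | fast default; raise to 1,000 for publication-grade supports |

Donor-group markers (which lineage names mean Amoebozoa, which mean a CPR
group, which mean a giant-virus lineage) are **configuration**
(`inst/extdata/donor_groups.tsv`), not code, because the published
grouping mixes ranks: phyla (*Parcubacteria*), subfamilies
(*Klosneuvirinae*), genera (Tupanvirus) and isolates. Tupanviruses are
deliberately their own subgroup rather than Klosneuvirinae, matching how
the two mimivirus isolates are reported. Classification walks the lineage
from the query upward and takes the *most specific* configured marker;
lineages with a superkingdom but no marker fall back to
`Other-<superkingdom>`; taxa absent from the taxonomy classify as
`Unclassified` with a warning (hit tables routinely carry stale taxon
ids), never an abort.

## The synthetic world

`simulate_bundle()` fabricates every pipeline input with planted truth.
Its defaults are a fixed statement of the world the screen targets, chosen
once:

* origin-class proportions echo the published taxonomic distribution
  (32.1% ORFan, 36.1% other eukaryote, 19.8% Amoebozoa, 10.07% bacteria
  plus 0.13% CPR — i.e. CPR = 1.3% of the bacterial fraction — 0.6%
  archaea, 0.79% giant virus, 0.01% other virus, 0.4% unclassified);
* intron counts are Poisson with class means 3.5 (eukaryote-like),
  2.7 (bacteria/archaea donors), 1.4 (giant-virus donors); planted
  *contaminant* genes average 0 introns because they are prokaryotic DNA,
  not transferred genes;
* read counts are zero-inflated Poisson (`p0 = 0.5`, `lambda = 12`); the
  source analysis reports no counts distribution, so this is a one-time
  realistic choice of a sparse transcriptome, not a tuned value;
* genome composition is random sequence at GC 41.7%; scaffolds carry
  `1 + Poisson(0.5)` genes, echoing the published ~1.5 genes/scaffold;
* each non-ORFan gene gets 1–20 hits whose surviving bit-score argmax is
  the planted donor with probability `1 − noise_eps`; a self-hit that
  outscores everything (removed only by self-taxon exclusion) and a decoy
  above the e-value threshold (removed only by the e-value filter) are
  planted so both filters are load-bearing in every recovery test;
* planted transfers sit **embedded among host genes**: after the i.i.d.
  class draw, a label-swapping repair (which preserves marginal class
  counts exactly) guarantees no non-contaminant scaffold is entirely
  bacterial-matching. This mirrors the biology being screened for —
  transferred genes co-localised with amoebal genes — and makes the
  planted contaminant scaffolds the *only* scaffolds satisfying the
  exclusion rule, so contaminant recovery has a defined truth.

What a green test does **not** establish: the generator has no residue-level
realism (hits are fabricated, not searched), no assembly error, no
paralogy, no database bias, and its taxonomy is a ~80-node stand-in.
Recovery results therefore validate the *pipeline logic* (filters,
tie-breaks, classification, tallies), not the biological error rate of
best-hit LST screening against a real database.

## Phylogenetic support

The congruence stage substitutes **neighbor joining on p-distances with
column-resampling bootstrap** for the maximum-likelihood trees of the
original analysis. This is a deliberate methodological substitution: NJ is
self-contained, exactly recovers additive distance matrices (which gives
an oracle the test suite exploits on 100 random trees), and answers the
same sister-clade question the published figures answer. The NJ
implementation pins two contracts that library implementations leave
unspecified: Q-matrix ties break on the smallest index pair, and negative
branch lengths are clamped to zero with the excess moved to the sibling
edge so path lengths are preserved.

`congruence_test()` midpoint-roots the tree (the published trees state no
outgroup convention) and calls a transfer *supported* iff the query's
sister clade contains at least one putative-donor leaf and no outgroup
leaf. The published figures colour branches by bootstrap without printing
a decision threshold, so this verdict rule is this package's
operationalisation and is labelled as such in its output.

## Numerical conventions

* `pct()` rounds half away from zero to one decimal — the only convention
  consistent with every printed share it reproduces (e.g. 811/2295 →
  35.3; 188/22483 → 0.8).
* N50 is scaffold-based: the shortest scaffold in the smallest set of
  longest scaffolds covering ≥ 50% of the assembly.
* GC excludes ambiguity codes from the denominator, making it a
  composition statistic rather than a coverage statistic.
* Multi-isoform genes are represented by the isoform with the most CDS
  segments (ties: smallest id) so each gene contributes one intron count.
* A p-distance pair with zero comparable columns is set to 1.0 with a
  warning rather than dropped, keeping the distance matrix complete.
* Zero-count genes may be absent from a counts table; they are read back
  as 0, not as errors.

## Known limitations

* No LCA/alien-index scoring; a single misleading best hit misclassifies
  a gene, which is inherent to the screened claim.
* Contamination detection is purely the totality rule — no coverage or
  composition evidence is used, so a short all-bacterial scaffold that is
  a genuine transfer hotspot would be (correctly per the rule, wrongly
  biologically) excluded; single-gene exclusions are flagged for audit.
* NJ congruence is a topology check; it does not test rate heterogeneity
  or alignment quality, and alignments are inputs.
* The rhizome writer emits Circos-format text files; rendering the figure
  is out of scope.
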