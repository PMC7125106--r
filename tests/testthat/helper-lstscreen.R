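# shared builders for the test suite; everything is generated in code

# write node/name tables from a data.frame(taxid, parent, rank, name)
write_tax_tables <- function(nodes) {
  nf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
  write.table(nodes[, c("taxid", "parent", "rank")], nf, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(nodes[, c("taxid", "name")], mf, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  list(nodes = nf, names = mf)
}

toy_nodes <- function() {
  data.frame(taxid = c(1L, 2L, 3L), parent = c(1L, 1L, 2L),
             rank = c("no_rank", "superkingdom", "phylum"),
             name = c("root", "Bacteria", "Proteobacteria"),
             stringsAsFactors = FALSE)
}

# quick assignment-frame constructor (defaults: assigned bacterial gene)
mk_assign <- function(gene_id, scaffold_id, status = "Assigned",
                      subject_taxid = NA_integer_,
                      superkingdom = NA_character_,
                      subgroup = NA_character_, is_cpr = FALSE,
                      is_giant_virus = FALSE, organism = NA_character_,
                      bitscore = 100, evalue = 1e-10,
                      subject_id = "ACC0000001") {
  out <- data.frame(gene_id = gene_id, scaffold_id = scaffold_id,
                    status = status, subject_id = subject_id,
                    pct_identity = 50, evalue = evalue, bitscore = bitscore,
                    subject_taxid = subject_taxid, organism = organism,
                    superkingdom = superkingdom, subgroup = subgroup,
                    is_cpr = is_cpr, is_giant_virus = is_giant_virus,
                    stringsAsFactors = FALSE)
  class(out) <- c("lst_assignments", "data.frame")
  out
}

# random binary tree with positive edge lengths and its additive matrix
rand_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.2, 2))
  D <- ape::cophenetic.phylo(tr)
  o <- sort(rownames(D))
  list(tree = ape::unroot(tr), D = D[o, o])
}

# map a simulator origin class to the expected superkingdom label
truth_superkingdom <- function(cls) {
  unname(c(orfan = NA_character_, eukaryote = "Eukaryota",
           amoebozoa = "Eukaryota", bacteria = "Bacteria", cpr = "Bacteria",
           archaea = "Archaea", giant_virus = "Viruses",
           other_virus = "Viruses", unclassified = "Unclassified",
           contaminant = "Bacteria")[cls])
}

# write a hit-table line with 13 fields
hit_line <- function(q, s, ev, bit, taxid, pid = 50.0, len = 100) {
  sprintf("%s\t%s\t%.1f\t%d\t10\t1\t1\t%d\t1\t%d\t%s\t%.1f\t%d",
          q, s, pid, len, len, len, format(ev, scientific = TRUE), bit, taxid)
}

# count lookup in a donor_tally level (0 when the key is absent)
tcount <- function(tl, level, key) {
  t <- tl[[level]]
  i <- match(key, t$key)
  if (is.na(i)) 0L else t$n[i]
}

# small shared bundle, built once per test run
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 20260909L, n_scaffolds = 400L)
      cache <<- simulate_bundle(cfg, file.path(tempdir(), "shared_bundle"))
    }
    cache
  }
})
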