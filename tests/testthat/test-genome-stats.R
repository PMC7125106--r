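write_fasta <- function(seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(unlist(mapply(function(n, s) c(paste0(">", n), s),
                           names(seqs), seqs, SIMPLIFY = FALSE)), f)
  f
}

# independent N50 oracle: exhaustive prefix sums over the sorted lengths
n50_oracle <- function(lens) {
  s <- sort(lens, decreasing = TRUE)
  cs <- cumsum(as.numeric(s))
  s[which(cs >= sum(as.numeric(lens)) / 2)[1]]
}

test_that("assembly_stats: closed forms and degenerate inputs", {
  f <- write_fasta(c(s1 = "GGCC"))
  st <- assembly_stats(f)
  expect_equal(st$gc_pct, 100)
  expect_equal(st$n50, 4L)
  expect_equal(st$max_len, 4L); expect_equal(st$min_len, 4L)

  expect_equal(assembly_stats(write_fasta(c(s = "ATGC")))$gc_pct, 50)
  # ambiguity codes excluded from the GC denominator
  expect_equal(assembly_stats(write_fasta(c(s = "ATGCNNNN")))$gc_pct, 50)

  # smallest set of longest scaffolds covering half of 40 bp is
  # {10, 9, 8} (27 >= 20), so N50 = 8
  lens <- c(10L, 9L, 8L, 7L, 6L)
  seqs <- setNames(vapply(lens, function(l)
    paste(rep("A", l), collapse = ""), ""), paste0("s", 1:5))
  expect_equal(assembly_stats(write_fasta(seqs))$n50, 8L)
  expect_equal(assembly_stats(write_fasta(seqs))$n50, n50_oracle(lens))

  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_error(assembly_stats(empty), "empty")
})

test_that("N50 and GC agree with brute-force oracles; order-invariant", {
  set.seed(9)
  for (i in 1:25) {
    lens <- sample(1:500, sample(1:20, 1), replace = TRUE)
    seqs <- vapply(lens, function(l)
      paste(sample(c("A", "C", "G", "T", "N"), l, TRUE), collapse = ""), "")
    names(seqs) <- sprintf("s%02d", seq_along(seqs))
    st <- assembly_stats(write_fasta(seqs))
    expect_equal(st$n50, n50_oracle(lens))
    chars <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1]],
                          levels = c("A", "C", "G", "T", "N")))
    expect_equal(st$gc_pct,
                 100 * (chars["G"] + chars["C"]) / sum(chars[1:4]),
                 ignore_attr = TRUE)
    rev_st <- assembly_stats(write_fasta(rev(seqs)))
    expect_equal(st[c("n50", "gc_pct", "total_bp", "max_len", "min_len")],
                 rev_st[c("n50", "gc_pct", "total_bp", "max_len", "min_len")])
  }
})

gff_text <- function(...) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", ...), f)
  f
}

test_that("parse_gene_models counts introns and picks the widest isoform", {
  f <- gff_text(
    "s1\tsrc\tgene\t1\t300\t.\t+\t.\tID=gA",
    "s1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=gA.t1;Parent=gA",
    "s1\tsrc\tCDS\t1\t300\t.\t+\t0\tID=gA.t1.c;Parent=gA.t1",
    "s1\tsrc\tgene\t400\t1000\t.\t-\t.\tID=gB",
    "s1\tsrc\tmRNA\t400\t1000\t.\t-\t.\tID=gB.t1;Parent=gB",
    "s1\tsrc\tCDS\t400\t450\t.\t-\t0\tID=gB.t1.c1;Parent=gB.t1",
    "s1\tsrc\tCDS\t500\t550\t.\t-\t0\tID=gB.t1.c2;Parent=gB.t1",
    "s1\tsrc\tCDS\t600\t650\t.\t-\t0\tID=gB.t1.c3;Parent=gB.t1",
    "s1\tsrc\tCDS\t700\t1000\t.\t-\t0\tID=gB.t1.c4;Parent=gB.t1",
    # second isoform with fewer exons must not represent the gene
    "s1\tsrc\tmRNA\t400\t1000\t.\t-\t.\tID=gB.t2;Parent=gB",
    "s1\tsrc\tCDS\t400\t1000\t.\t-\t0\tID=gB.t2.c1;Parent=gB.t2")
  m <- parse_gene_models(f)
  expect_equal(m$intron_count[m$gene_id == "gA"], 0L)
  expect_equal(m$intron_count[m$gene_id == "gB"], 3L)
  expect_equal(m$n_exons[m$gene_id == "gB"], 4L)
  expect_equal(m$protein_length[m$gene_id == "gA"], 100L)

  bad <- gff_text(
    "s1\tsrc\tgene\t1\t300\t.\t+\t.\tID=gA",
    "s1\tsrc\tCDS\t1\t300\t.\t+\t0\tID=x;Parent=ghost.t1")
  expect_error(parse_gene_models(bad), "unknown parent")
})

test_that("planted exon counts are recovered from the simulated GFF3", {
  b <- shared_bundle()
  m <- parse_gene_models(b$paths$gff3)
  tr <- b$truth
  expect_equal(m$intron_count[match(tr$gene_id, m$gene_id)], tr$intron_count)
})

test_that("mean_introns_by_group: closed forms and recombination", {
  a <- rbind(mk_assign(c("g1", "g2"), "s1", superkingdom = "Bacteria",
                       subgroup = "Proteobacteria", subject_taxid = 31L),
             mk_assign(c("g3", "g4"), "s1", superkingdom = "Eukaryota",
                       subgroup = "Amoebozoa", subject_taxid = 14L))
  class(a) <- c("lst_assignments", "data.frame")
  m <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  intron_count = c(2L, 3L, 0L, 0L))
  got <- mean_introns_by_group(m, a)
  expect_equal(got[["bacteria/archaea"]], 2.5)
  expect_equal(got[["eukaryote-like"]], 0)
  # weighted group means recombine to the global mean; order-invariant
  w <- table(default_intron_grouping(a))[names(got)]
  expect_equal(sum(got * as.integer(w)) / sum(w), mean(m$intron_count))
  perm <- sample(nrow(m))
  expect_equal(mean_introns_by_group(m[perm, ], a), got)
  expect_error(mean_introns_by_group(
    data.frame(gene_id = "zz", intron_count = 1L), a), "without assignments")
})

test_that("length_filter_stats uses an inclusive 100 aa boundary", {
  m <- data.frame(gene_id = c("a", "b", "c"),
                  protein_length = c(99L, 100L, 101L))
  got <- length_filter_stats(m)
  expect_equal(got$count, 2L)
  expect_equal(got$proportion, pct(2, 3))
  expect_warning(empty <- length_filter_stats(m[0, ]), "undefined")
  expect_equal(empty$count, 0L)
  expect_true(is.na(empty$proportion))
})
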