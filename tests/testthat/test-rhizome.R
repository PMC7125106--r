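test_that("pct rounds half away from zero to one decimal", {
  expect_equal(pct(2295, 22483), 10.2)
  expect_equal(pct(811, 2295), 35.3)
  expect_equal(pct(30, 2295), 1.3)
  expect_equal(pct(0, 10), 0)
  expect_equal(pct(1, 800), 0.1)       # 0.125 -> 0.1
  expect_equal(pct(3, 2000), 0.2)      # 0.15 rounds away from zero
  expect_error(pct(1, 0), "denominator")
})

test_that("tally_donors counts at all three levels", {
  empty <- tally_donors(mk_assign("x", "s")[0, ])
  expect_equal(empty$total_genes, 0L)
  expect_equal(empty$total_bacterial, 0L)
  expect_equal(nrow(empty$superkingdom), 0L)

  fix <- expand_organism_counts(lst_fixture("fig4_virus_best_hits.tsv"))
  tl <- tally_donors(fix)
  expect_equal(tl$total_genes, 188L)
  klos <- tl$subgroup$n[tl$subgroup$key == "Viruses|Klosneuvirinae"]
  expect_equal(klos, 101L)
  expect_equal(tl$organism$n[tl$organism$key == "Bodo saltans virus"], 69L)
  expect_equal(tl$organism$n[tl$organism$key == "Orpheovirus IHUMI-LCC2"], 34L)
  expect_equal(sum(fix$is_giant_virus), 183L)   # phages/poxvirus excluded

  # planted proportions tally exactly on synthetic data
  b <- shared_bundle()
  tax <- load_taxonomy(b$paths$nodes, b$paths$names)
  asg <- assign_genes(filter_hits(parse_hits(b$paths$hits), 1e-3,
                                  b$self_taxid), b$catalog, tax)
  tl2 <- tally_donors(asg)
  sk_truth <- table(truth_superkingdom(b$truth$origin_class), useNA = "no")
  for (k in names(sk_truth))
    expect_equal(tcount(tl2, "superkingdom", k),
                 as.integer(sk_truth[[k]]), info = k)
  expect_equal(tcount(tl2, "superkingdom", "ORFan"),
               sum(b$truth$origin_class == "orfan"))
  # partition: superkingdom bins + ORFan = total
  expect_equal(sum(tl2$superkingdom$n), tl2$total_genes)
})

test_that("cog_tally counts category letters", {
  a <- mk_assign(c("g1", "g2", "g3", "g4"), "s1")
  empty <- cog_tally(data.frame(gene_id = character(0),
                                categories = character(0)), a)
  expect_equal(empty[["unassigned"]], 4L)

  m <- data.frame(gene_id = c("g1", "g2", "g3"),
                  categories = c("S", "ST", "T"))
  got <- cog_tally(m, a)
  expect_equal(got[["S"]], 2L)          # g2 counted once per letter
  expect_equal(got[["T"]], 2L)
  expect_equal(got[["unassigned"]], 1L)
  expect_warning(bad <- cog_tally(
    data.frame(gene_id = "g1", categories = "s"), a), "unknown COG")
  expect_equal(bad[["other"]], 1L)
})

test_that("write_rhizome emits deterministic karyotype and link files", {
  b <- shared_bundle()
  tax <- load_taxonomy(b$paths$nodes, b$paths$names)
  asg <- assign_genes(filter_hits(parse_hits(b$paths$hits), 1e-3,
                                  b$self_taxid), b$catalog, tax)
  models <- parse_gene_models(b$paths$gff3)
  k1 <- tempfile(); l1 <- tempfile(); k2 <- tempfile(); l2 <- tempfile()
  res <- write_rhizome(asg, models, b$scaffold_lengths,
                       karyotype_path = k1, links_path = l1)
  planted <- b$truth[b$truth$origin_class == "giant_virus", ]
  expect_equal(res$n_links, nrow(planted))
  expect_equal(res$n_scaffolds, length(unique(planted$scaffold_id)))
  write_rhizome(asg, models, b$scaffold_lengths,
                karyotype_path = k2, links_path = l2)
  expect_identical(readLines(l1), readLines(l2))    # byte-identical
  expect_identical(readLines(k1), readLines(k2))

  # zero selected genes -> empty links file with a valid header
  none <- write_rhizome(asg, models, b$scaffold_lengths,
                        donor_filter = function(a) rep(FALSE, nrow(a)),
                        karyotype_path = k1, links_path = l1)
  expect_equal(none$n_links, 0L)
  expect_match(readLines(l1)[1], "^# rhizome links")
  expect_equal(length(readLines(l1)), 1L)

  # interval outside scaffold bounds is an error
  short <- b$scaffold_lengths
  short[unique(planted$scaffold_id)[1]] <- 1L
  expect_error(write_rhizome(asg, models, short,
                             karyotype_path = k1, links_path = l1),
               "outside scaffold")
})

test_that("summary_report shares are consistent and sum to ~100", {
  b <- shared_bundle()
  tax <- load_taxonomy(b$paths$nodes, b$paths$names)
  asg <- assign_genes(filter_hits(parse_hits(b$paths$hits), 1e-3,
                                  b$self_taxid), b$catalog, tax)
  rep <- summary_report(tally_donors(asg))
  h <- rep$headline
  shares <- h$share[h$label %in% c("eukaryote_share", "bacteria_share",
                                   "archaea_share", "virus_share",
                                   "unclassified_share", "orfan_share")]
  expect_lt(abs(sum(shares) - 100), 0.3)           # rounding slack only

  allorf <- mk_assign(c("g1", "g2"), "s1", status = "ORFan",
                      subject_taxid = NA_integer_)
  h0 <- summary_report(tally_donors(allorf))$headline
  expect_equal(h0$share[h0$label == "orfan_share"], 100)
  expect_true(all(h0$share[h0$label %in% c("eukaryote_share",
                                           "bacteria_share",
                                           "virus_share")] == 0))
  # JSON/TSV writers round-trip
  ts <- tempfile(); js <- tempfile()
  write_summary(rep, ts, js)
  expect_equal(nrow(read.delim(ts)), nrow(h))
  expect_true(jsonlite::validate(paste(readLines(js), collapse = "")))
})
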