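#' Run the full lateral-sequence-transfer screen
#'
#' End-to-end orchestration: load taxonomy and gene models, parse and
#' filter hits, call best hits and ORFans, exclude contaminant scaffolds,
#' attach expression, compute assembly/intron statistics, tally donors, and
#' write the summary report plus rhizome files into `outdir`. Every
#' filter's in/out counts are logged via `message()`.
#'
#' @param fasta,gff3,hits,counts,node_table,name_table Input paths (see the
#'   reader functions for formats).
#' @param group_config Donor-group marker config path (default: shipped
#'   scheme).
#' @param outdir Output directory.
#' @param min_reads Transcription-call threshold (default 5 reads).
#' @param max_evalue Hit e-value threshold (default 1e-3).
#' @param contaminant_rank Rank at which "same bacteria" is resolved.
#' @param self_taxids Taxon ids excluded as self-hits.
#' @param rhizome_filter Predicate selecting rhizome donors (default:
#'   giant-virus best hits).
#' @return Invisibly, a list with assignments, verdicts, tally, report,
#'   models, stats, and output paths.
#' @export
run_lst_screen <- function(fasta, gff3, hits, counts, node_table, name_table,
                           group_config = default_group_config(),
                           outdir = ".", min_reads = 5L, max_evalue = 1e-3,
                           contaminant_rank = "species",
                           self_taxids = integer(0),
                           rhizome_filter = function(a)
                             !is.na(a$is_giant_virus) & a$is_giant_virus) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tree <- load_taxonomy(node_table, name_table)
  cfg <- load_group_config(group_config)
  models <- parse_gene_models(gff3)
  catalog <- models[, c("gene_id", "scaffold_id")]
  stats <- assembly_stats(fasta)
  message("inputs: ", nrow(catalog), " genes on ", stats$n_scaffolds,
          " scaffolds")
  h <- parse_hits(hits)
  message("hits: ", nrow(h), " records parsed")
  h <- filter_hits(h, max_evalue = max_evalue, self_taxids = self_taxids)
  message("hits: ", nrow(h), " records after e-value/self filtering")
  asg <- assign_genes(h, catalog, tree, cfg)
  message("assignment: ", sum(asg$status == "Assigned"), " assigned, ",
          sum(asg$status == "ORFan"), " ORFan")
  verdicts <- flag_contaminants(asg, tree, rank = contaminant_rank)
  kept <- apply_verdicts(asg, verdicts)
  cnt <- load_counts(counts)
  kept <- flag_transcribed(kept, cnt, min_reads = min_reads)
  message("expression: ", sum(kept$expressed), " genes transcribed (>= ",
          min_reads, " reads)")
  tly <- tally_donors(kept)
  lstats <- length_filter_stats(models[models$gene_id %in% kept$gene_id, ,
                                       drop = FALSE])
  candidates <- rank_expressed(kept, function(a)
    !is.na(a$superkingdom) & a$superkingdom != "Eukaryota")
  report <- summary_report(tly, stats = stats, length_stats = lstats,
                           expression = candidates, verdicts = verdicts)
  introns <- mean_introns_by_group(
    models[models$gene_id %in% kept$gene_id, , drop = FALSE], kept)
  seqs <- Biostrings::readDNAStringSet(fasta)
  scaffold_lengths <- stats::setNames(Biostrings::width(seqs),
                                      sub("\\s.*$", "", names(seqs)))
  out <- list(
    assignments = file.path(outdir, "assignments.tsv"),
    verdicts = file.path(outdir, "scaffold_verdicts.tsv"),
    summary_tsv = file.path(outdir, "summary.tsv"),
    summary_json = file.path(outdir, "summary.json"),
    candidates = file.path(outdir, "expressed_candidates.tsv"),
    introns = file.path(outdir, "intron_means.tsv"),
    karyotype = file.path(outdir, "rhizome_karyotype.txt"),
    links = file.path(outdir, "rhizome_links.txt"))
  write_assignments(kept, out$assignments)
  utils::write.table(verdicts, out$verdicts, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  write_summary(report, out$summary_tsv, out$summary_json)
  utils::write.table(candidates, out$candidates, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(data.frame(group = names(introns),
                                mean_introns = round(introns, 1)),
                     out$introns, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_rhizome(kept, models, scaffold_lengths, rhizome_filter,
                karyotype_path = out$karyotype, links_path = out$links)
  invisible(list(assignments = kept, verdicts = verdicts, tally = tly,
                 report = report, models = models, stats = stats,
                 intron_means = introns, candidates = candidates,
                 paths = out))
}
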