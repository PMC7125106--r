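#' Paths to the bundled worked-example fixtures
#'
#' Small plain-text tables transcribing counts printed in the source
#' analysis (per-organism virus best-hit counts; the expressed bacterial
#' and viral candidate tables; the printed numerator/denominator pairs).
#' They are inputs to the worked examples, not outputs of this package.
#'
#' @param name File name under `extdata`.
#' @return Absolute path.
#' @export
lst_fixture <- function(name) {
  system.file("extdata", name, package = "lstscreen", mustWork = TRUE)
}

#' Expand a per-organism count table into per-gene assignments
#'
#' Each organism name is resolved to a taxid in [synthetic_taxonomy()] and
#' classified through the donor-group scheme, yielding one `Assigned` row
#' per counted gene — so tallies over the result exercise the real
#' classifier, not transcribed labels.
#'
#' @param counts data.frame with columns `organism`, `n_genes` — or a path
#'   to such a TSV.
#' @param tree Taxonomy (default [synthetic_taxonomy()]).
#' @param config Donor-group config.
#' @return An `lst_assignments` data.frame.
#' @export
expand_organism_counts <- function(counts, tree = synthetic_taxonomy(),
                                   config = load_group_config()) {
  if (is.character(counts))
    counts <- utils::read.delim(counts, stringsAsFactors = FALSE)
  taxid <- tree$nodes$taxid[match(counts$organism, tree$nodes$name)]
  if (anyNA(taxid))
    stop("organism(s) absent from taxonomy: ",
         paste(counts$organism[is.na(taxid)], collapse = ", "))
  n <- counts$n_genes
  gene_taxid <- rep(taxid, n)
  out <- data.frame(
    gene_id = sprintf("fx%06d", seq_along(gene_taxid)),
    scaffold_id = sprintf("fxscf%05d", seq_along(gene_taxid)),
    status = "Assigned",
    subject_id = sprintf("FIX%06d.1", seq_along(gene_taxid)),
    pct_identity = NA_real_, evalue = NA_real_, bitscore = NA_real_,
    subject_taxid = gene_taxid,
    organism = rep(counts$organism, n),
    stringsAsFactors = FALSE)
  out <- cbind(out, classify_taxa(tree, gene_taxid, config))
  rownames(out) <- NULL
  class(out) <- c("lst_assignments", "data.frame")
  out
}

#' Load a printed candidate table as assignments with read counts
#'
#' Reads a fixture like the expressed-candidate tables (columns `gene_id`,
#' `best_hit`, `function`, `organism`, optionally `read_count`), resolves
#' organisms against the synthetic taxonomy and classifies them. When read
#' counts are present they are attached via [flag_transcribed()] semantics.
#'
#' @param path Fixture TSV path.
#' @inheritParams expand_organism_counts
#' @param min_reads Transcription threshold applied when counts exist.
#' @return An `lst_assignments` data.frame.
#' @export
load_candidate_fixture <- function(path, tree = synthetic_taxonomy(),
                                   config = load_group_config(),
                                   min_reads = 5L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  taxid <- tree$nodes$taxid[match(tab$organism, tree$nodes$name)]
  if (anyNA(taxid))
    stop("organism(s) absent from taxonomy: ",
         paste(tab$organism[is.na(taxid)], collapse = ", "))
  out <- data.frame(
    gene_id = tab$gene_id,
    scaffold_id = sprintf("fxscf%05d", seq_len(nrow(tab))),
    status = "Assigned",
    subject_id = tab$best_hit,
    pct_identity = NA_real_, evalue = NA_real_, bitscore = NA_real_,
    subject_taxid = taxid,
    organism = tab$organism,
    annotation = tab[["function"]],
    stringsAsFactors = FALSE)
  out <- cbind(out, classify_taxa(tree, taxid, config))
  class(out) <- c("lst_assignments", "data.frame")
  if (!is.null(tab$read_count)) {
    cnt <- stats::setNames(as.integer(tab$read_count), tab$gene_id)
    out <- flag_transcribed(out, cnt, min_reads = min_reads)
  }
  out
}
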