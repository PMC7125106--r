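#' Percentage with the report's rounding convention
#'
#' 100 * n / d rounded half away from zero to one decimal — the only
#' convention consistent with every printed share this package reproduces
#' (e.g. 811/2295 -> 35.3, 188/22483 -> 0.8).
#'
#' @param numerator,denominator Counts; `denominator` must be > 0.
#' @return Percentage rounded to one decimal.
#' @export
pct <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("pct: denominator must be > 0")
  x <- 100 * numerator / denominator
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Tally genes per donor group and organism
#'
#' Deterministic counts at three grouping levels: superkingdom (with ORFan
#' and Unclassified as their own bins), (superkingdom, subgroup), and
#' best-hit organism.
#'
#' @param assignments An `lst_assignments` data.frame (normally
#'   post-contamination-filter).
#' @return List of class `donor_tally`: `superkingdom`, `subgroup`,
#'   `organism` (named count tables as data.frames), `total_genes`,
#'   `total_bacterial`.
#' @export
tally_donors <- function(assignments) {
  a <- assignments
  sk <- ifelse(a$status == "ORFan", "ORFan", a$superkingdom)
  cnt <- function(keys) {
    if (length(keys) == 0L || all(is.na(keys)))
      return(data.frame(key = character(0), n = integer(0)))
    t <- table(keys, useNA = "no")
    out <- data.frame(key = names(t), n = as.integer(t),
                      stringsAsFactors = FALSE)
    out[order(out$key, method = "radix"), , drop = FALSE]
  }
  sub_keys <- ifelse(a$status == "Assigned",
                     paste(a$superkingdom, a$subgroup, sep = "|"),
                     NA_character_)
  org_keys <- ifelse(a$status == "Assigned", a$organism, NA_character_)
  structure(list(
    superkingdom = cnt(sk),
    subgroup = cnt(sub_keys),
    organism = cnt(org_keys),
    total_genes = nrow(a),
    total_bacterial = sum(!is.na(a$superkingdom) &
                            a$superkingdom == "Bacteria")),
    class = "donor_tally")
}

#' @export
print.donor_tally <- function(x, ...) {
  cat("donor_tally:", x$total_genes, "genes,",
      x$total_bacterial, "bacterial\n")
  print(x$superkingdom)
  invisible(x)
}

# count for one key of a donor_tally level, 0 if absent
tally_count <- function(tally, level, key) {
  t <- tally[[level]]
  i <- match(key, t$key)
  if (is.na(i)) 0L else t$n[i]
}

#' Tally COG functional categories
#'
#' @param cog_map data.frame with columns `gene_id`, `categories` (one or
#'   more single-letter COG categories, e.g. "ST"; a gene with two letters
#'   is counted once per letter).
#' @param assignments An `lst_assignments` data.frame defining the gene
#'   universe.
#' @return Named integer vector of counts per category letter, plus an
#'   `unassigned` entry; letters outside A-Z trigger a warning and are
#'   bucketed as `other`.
#' @export
cog_tally <- function(cog_map, assignments) {
  genes <- assignments$gene_id
  m <- cog_map[cog_map$gene_id %in% genes, , drop = FALSE]
  letters_per_gene <- strsplit(m$categories, "", fixed = TRUE)
  all_letters <- unlist(letters_per_gene)
  bad <- !(all_letters %in% LETTERS)
  if (any(bad)) {
    warning("unknown COG category letter(s): ",
            paste(unique(all_letters[bad]), collapse = ", "),
            "; bucketed as 'other'")
    all_letters[bad] <- "other"
  }
  out <- table(all_letters)
  res <- stats::setNames(as.integer(out), names(out))
  res["unassigned"] <- sum(!(genes %in% m$gene_id))
  res
}

#' Write Circos-style rhizome karyotype and link files
#'
#' One karyotype band per scaffold carrying at least one selected gene; one
#' link per selected gene, mapping its span on the scaffold (1-based
#' inclusive, as in GFF3) to its donor label. Output ordering is
#' deterministic (scaffold id, then start), so identical inputs yield
#' byte-identical files.
#'
#' Karyotype fields: `chr - scaffold_id scaffold_id 0 length class`.
#' Link fields: `scaffold_id start end donor_organism subgroup class`.
#'
#' @param assignments An `lst_assignments` data.frame.
#' @param models Gene models (for gene spans) from [parse_gene_models()].
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @param donor_filter Predicate on the assignment data.frame selecting the
#'   donor set to draw (default: giant-virus best hits).
#' @param karyotype_path,links_path Output paths.
#' @return Invisibly, a list with the number of links and scaffolds written.
#' @export
write_rhizome <- function(assignments, models, scaffold_lengths,
                          donor_filter = function(a)
                            !is.na(a$is_giant_virus) & a$is_giant_virus,
                          karyotype_path, links_path) {
  sel <- donor_filter(assignments)
  sel[is.na(sel)] <- FALSE
  a <- assignments[sel, , drop = FALSE]
  i <- match(a$gene_id, models$gene_id)
  if (anyNA(i))
    stop("selected genes without gene models: ",
         paste(utils::head(a$gene_id[is.na(i)], 5), collapse = ", "))
  start <- models$start[i]; end <- models$end[i]
  len <- scaffold_lengths[a$scaffold_id]
  if (anyNA(len))
    stop("unknown scaffold length for: ",
         paste(utils::head(unique(a$scaffold_id[is.na(len)]), 5),
               collapse = ", "))
  if (any(start < 1 | end > len))
    stop("gene interval outside scaffold bounds")
  cls <- gsub("[^A-Za-z0-9]+", "_", tolower(a$subgroup))
  o <- order(a$scaffold_id, start, method = "radix")
  links <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   a$scaffold_id[o], start[o], end[o],
                   a$organism[o], a$subgroup[o], cls[o])
  scf <- sort(unique(a$scaffold_id), method = "radix")
  kary <- sprintf("chr - %s %s 0 %d scaffold", scf, scf,
                  as.integer(scaffold_lengths[scf]))
  writeLines(c("# rhizome karyotype: chr - id label start end class", kary),
             karyotype_path)
  writeLines(c("# rhizome links: scaffold start end organism subgroup class",
               links), links_path)
  invisible(list(n_links = length(links), n_scaffolds = length(scf)))
}

#' Structured screening summary
#'
#' Headline counts and [pct()] shares: superkingdom shares of total genes
#' (plus Amoebozoa within eukaryotes and ORFan share), bacterial phylum and
#' CPR shares of the post-filter bacterial total, and the protein-length
#' filter share.
#'
#' @param tally A `donor_tally` (post-contamination-filter).
#' @param stats Optional `assembly_stats`.
#' @param length_stats Optional result of [length_filter_stats()].
#' @param expression Optional result of [rank_expressed()] (candidate list).
#' @param verdicts Optional `scaffold_verdicts`.
#' @return List of class `lst_report` with elements `headline` (data.frame
#'   label/count/share) and the inputs.
#' @export
summary_report <- function(tally, stats = NULL, length_stats = NULL,
                           expression = NULL, verdicts = NULL) {
  tg <- tally$total_genes
  tb <- tally$total_bacterial
  sk_row <- function(label, key) {
    n <- tally_count(tally, "superkingdom", key)
    data.frame(label = label, count = n,
               share = if (tg > 0) pct(n, tg) else NA_real_)
  }
  rows <- rbind(
    data.frame(label = "total_genes", count = tg, share = NA_real_),
    sk_row("eukaryote_share", "Eukaryota"),
    {
      n <- tally_count(tally, "subgroup", "Eukaryota|Amoebozoa")
      data.frame(label = "amoebozoa_share", count = n,
                 share = if (tg > 0) pct(n, tg) else NA_real_)
    },
    sk_row("bacteria_share", "Bacteria"),
    sk_row("archaea_share", "Archaea"),
    sk_row("virus_share", "Viruses"),
    sk_row("unclassified_share", "Unclassified"),
    sk_row("orfan_share", "ORFan"))
  # phylum / CPR shares of the bacterial total
  sub <- tally$subgroup
  bac <- sub[startsWith(sub$key, "Bacteria|"), , drop = FALSE]
  if (nrow(bac) && tb > 0) {
    cfg <- load_group_config()
    cpr_groups <- paste0("Bacteria|", cfg$subgroup[cfg$is_cpr])
    rows <- rbind(rows, data.frame(
      label = paste0("bacterial_phylum:", sub("^Bacteria\\|", "", bac$key)),
      count = bac$n, share = pct(bac$n, tb)))
    n_cpr <- sum(bac$n[bac$key %in% cpr_groups])
    rows <- rbind(rows, data.frame(label = "cpr_share_of_bacterial",
                                   count = n_cpr, share = pct(n_cpr, tb)))
  }
  if (!is.null(length_stats))
    rows <- rbind(rows, data.frame(label = "length_ge_threshold",
                                   count = length_stats$count,
                                   share = length_stats$proportion))
  rownames(rows) <- NULL
  structure(list(headline = rows, tally = tally, assembly = stats,
                 length_stats = length_stats, expression = expression,
                 verdicts = verdicts),
            class = "lst_report")
}

#' @export
print.lst_report <- function(x, ...) {
  cat("LST screening summary\n")
  print(x$headline, row.names = FALSE)
  invisible(x)
}

#' Write a summary report as TSV and JSON
#'
#' @param report An `lst_report`.
#' @param tsv_path,json_path Output paths (either may be NULL to skip).
#' @export
write_summary <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(report$headline, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  if (!is.null(json_path)) {
    payload <- list(
      headline = report$headline,
      assembly = if (!is.null(report$assembly))
        unclass(report$assembly) else NULL)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(c(tsv_path, json_path))
}
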