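HIT_COLS <- c("query_id", "subject_id", "pct_identity", "aln_len",
              "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
              "evalue", "bitscore", "subject_taxid")

#' Parse a tabular homology hit file
#'
#' Reads the standard 12-column tabular output of a protein search extended
#' with a 13th column holding the subject taxon id. Lines starting with `#`
#' are ignored; record order is preserved.
#'
#' @param path Path to the hit table.
#' @return data.frame with columns `query_id, subject_id, pct_identity,
#'   aln_len, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#'   bitscore, subject_taxid`.
#' @export
parse_hits <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- data.frame(matrix(nrow = 0, ncol = 13))
    names(out) <- HIT_COLS
    out$query_id <- character(0); out$subject_id <- character(0)
    for (cc in c("pct_identity", "evalue", "bitscore")) out[[cc]] <- numeric(0)
    for (cc in c("aln_len", "mismatch", "gapopen", "qstart", "qend",
                 "sstart", "send", "subject_taxid")) out[[cc]] <- integer(0)
    return(out[, HIT_COLS])
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 13L)) {
    bad <- which(nf != 13L)[1L]
    stop("hit file line ", lineno[bad], ": expected 13 tab-separated fields, ",
         "got ", nf[bad])
  }
  m <- matrix(unlist(parts), ncol = 13L, byrow = TRUE)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("hit file line ", lineno[bad], ": non-numeric ", what,
           " '", m[bad, j], "'")
    }
    v
  }
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = num(3, "identity"), aln_len = as.integer(num(4, "length")),
    mismatch = as.integer(num(5, "mismatch")),
    gapopen = as.integer(num(6, "gapopen")),
    qstart = as.integer(num(7, "qstart")), qend = as.integer(num(8, "qend")),
    sstart = as.integer(num(9, "sstart")), send = as.integer(num(10, "send")),
    evalue = num(11, "e-value"), bitscore = num(12, "bit score"),
    subject_taxid = as.integer(num(13, "subject taxid")),
    stringsAsFactors = FALSE)
  if (any(out$evalue < 0)) stop("negative e-value in hit file")
  if (any(out$aln_len < 1)) stop("alignment length < 1 in hit file")
  out
}

#' Filter hits by e-value and self-taxon exclusion
#'
#' Keeps records with `evalue <= max_evalue` (boundary inclusive) whose
#' subject taxon is not in `self_taxids`. Self-hit exclusion matters once the
#' query genome itself enters public databases: without it every gene's best
#' hit is its own deposited sequence.
#'
#' @param hits data.frame from [parse_hits()].
#' @param max_evalue E-value threshold (default 1e-3).
#' @param self_taxids Integer vector of taxon ids to drop as self-hits.
#' @return Filtered data.frame, original order preserved.
#' @export
filter_hits <- function(hits, max_evalue = 1e-3, self_taxids = integer(0)) {
  stopifnot(max_evalue > 0)
  hits[hits$evalue <= max_evalue & !(hits$subject_taxid %in% self_taxids), ,
       drop = FALSE]
}

#' Best hit for one gene
#'
#' The record maximising bit score; ties broken by smaller e-value, then by
#' lexicographically smallest subject id (C locale), so the choice is
#' deterministic under any input permutation.
#'
#' @param hits Non-empty data.frame of hits for a single gene.
#' @return One-row data.frame.
#' @export
best_hit <- function(hits) {
  if (nrow(hits) == 0L) stop("best_hit: no surviving records")
  o <- order(-hits$bitscore, hits$evalue,
             xtfrm(factor(hits$subject_id,
                          levels = sort(unique(hits$subject_id),
                                        method = "radix"))),
             method = "radix")
  hits[o[1L], , drop = FALSE]
}

#' Assign every predicted gene an ORFan/donor outcome
#'
#' Genes with zero surviving hits are ORFans; all others carry their best hit
#' and its donor-group classification. Every catalog gene appears exactly
#' once in the output; a hit whose query is absent from the catalog is an
#' error.
#'
#' @param hits Filtered hit data.frame (see [filter_hits()]).
#' @param gene_catalog data.frame with columns `gene_id`, `scaffold_id`
#'   listing every predicted gene.
#' @param tree A `taxonomy_tree`.
#' @param config Donor-group marker config.
#' @return data.frame of class `lst_assignments`: gene_id, scaffold_id,
#'   status (ORFan/Assigned), subject_id, pct_identity, evalue, bitscore,
#'   subject_taxid, organism, superkingdom, subgroup, is_cpr, is_giant_virus.
#' @export
assign_genes <- function(hits, gene_catalog, tree,
                         config = load_group_config()) {
  stopifnot(all(c("gene_id", "scaffold_id") %in% names(gene_catalog)))
  if (anyDuplicated(gene_catalog$gene_id))
    stop("duplicate gene_id in catalog")
  orphan <- setdiff(unique(hits$query_id), gene_catalog$gene_id)
  if (length(orphan))
    stop("hits for genes absent from the catalog: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  # vectorised per-gene best hit: global sort, then first row per query
  if (nrow(hits)) {
    o <- order(xtfrm(factor(hits$query_id,
                            levels = sort(unique(hits$query_id),
                                          method = "radix"))),
               -hits$bitscore, hits$evalue,
               xtfrm(factor(hits$subject_id,
                            levels = sort(unique(hits$subject_id),
                                          method = "radix"))),
               method = "radix")
    best <- hits[o, , drop = FALSE]
    best <- best[!duplicated(best$query_id), , drop = FALSE]
  } else {
    best <- hits
  }
  i <- match(gene_catalog$gene_id, best$query_id)
  out <- data.frame(
    gene_id = gene_catalog$gene_id,
    scaffold_id = gene_catalog$scaffold_id,
    status = ifelse(is.na(i), "ORFan", "Assigned"),
    subject_id = best$subject_id[i],
    pct_identity = best$pct_identity[i],
    evalue = best$evalue[i],
    bitscore = best$bitscore[i],
    subject_taxid = best$subject_taxid[i],
    stringsAsFactors = FALSE)
  grp <- data.frame(superkingdom = NA_character_, subgroup = NA_character_,
                    is_cpr = NA, is_giant_virus = NA)[rep(1L, nrow(out)), ]
  assigned <- !is.na(i)
  if (any(assigned))
    grp[assigned, ] <- classify_taxa(tree, out$subject_taxid[assigned], config)
  out$organism <- tree$nodes$name[tree$idx[as.character(out$subject_taxid)]]
  out$organism[!assigned] <- NA_character_
  out <- cbind(out, grp)
  rownames(out) <- NULL
  class(out) <- c("lst_assignments", "data.frame")
  out
}

#' Write a per-gene assignment table
#'
#' @param assignments An `lst_assignments` data.frame.
#' @param path Output TSV path.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
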