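#' Load a per-gene read-count table
#'
#' Two-column TSV `(gene_id, count)` in the dialect of common counting
#' tools: summary rows whose gene id starts with `__` (e.g. `__no_feature`)
#' are skipped.
#'
#' @param path Path to the counts TSV (no header).
#' @return Named integer vector of read counts.
#' @export
load_counts <- function(path) {
  tab <- utils::read.delim(path, header = FALSE,
                           col.names = c("gene_id", "count"),
                           colClasses = c("character", "character"),
                           quote = "")
  tab <- tab[!startsWith(tab$gene_id, "__"), , drop = FALSE]
  cnt <- suppressWarnings(as.numeric(tab$count))
  if (anyNA(cnt) || any(cnt != floor(cnt)))
    stop("non-integer read count in ", path)
  if (any(cnt < 0)) stop("negative read count in ", path)
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene id in counts table: ",
         tab$gene_id[duplicated(tab$gene_id)][1L])
  stats::setNames(as.integer(cnt), tab$gene_id)
}

#' Flag transcribed genes
#'
#' A gene is called transcribed if covered by at least `min_reads` reads
#' (boundary inclusive). Genes absent from the counts table get a read
#' count of 0 rather than an error, because counting tools omit zero rows
#' in some dialects.
#'
#' @param assignments An `lst_assignments` data.frame.
#' @param counts Named integer vector from [load_counts()].
#' @param min_reads Transcription threshold (default 5).
#' @return `assignments` with `read_count` and `expressed` columns set.
#' @export
flag_transcribed <- function(assignments, counts, min_reads = 5L) {
  stopifnot(min_reads >= 1L)
  rc <- unname(counts[assignments$gene_id])
  rc[is.na(rc)] <- 0L
  assignments$read_count <- rc
  assignments$expressed <- rc >= min_reads
  assignments
}

#' Rank expressed transfer candidates by read count
#'
#' @param assignments Assignments carrying `read_count`/`expressed` (see
#'   [flag_transcribed()]).
#' @param donor_filter Predicate: a function taking the assignment
#'   data.frame and returning a logical vector selecting candidate rows
#'   (e.g. bacterial donors). Default selects every assigned gene.
#' @param top_n Keep at most this many rows (default all).
#' @return data.frame ordered by descending read count, ties by gene id.
#' @export
rank_expressed <- function(assignments,
                           donor_filter = function(a) a$status == "Assigned",
                           top_n = Inf) {
  if (nrow(assignments) == 0L) return(assignments)
  stopifnot(!is.null(assignments$read_count))
  sel <- assignments$expressed & donor_filter(assignments)
  sel[is.na(sel)] <- FALSE
  out <- assignments[sel, , drop = FALSE]
  o <- order(-out$read_count,
             xtfrm(factor(out$gene_id,
                          levels = sort(unique(out$gene_id),
                                        method = "radix"))),
             method = "radix")
  out <- out[o, , drop = FALSE]
  if (is.finite(top_n)) out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}
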