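#' Assembly statistics from a FASTA file
#'
#' N50 is the length of the shortest sequence in the smallest set of longest
#' sequences whose summed length reaches half the assembly; GC is computed
#' over unambiguous A/C/G/T calls only, so ambiguity codes never dilute the
#' composition.
#'
#' @param fasta Path to a (multi-)FASTA of scaffolds.
#' @return List of class `assembly_stats`: total_bp, gc_pct, n_scaffolds,
#'   max_len, min_len, n50.
#' @export
assembly_stats <- function(fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta)
  w <- Biostrings::width(seqs)
  if (any(w == 0L)) stop("zero-length record in ", fasta)
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE, collapse = TRUE)
  acgt <- sum(freq[c("A", "C", "G", "T")])
  gc <- if (acgt > 0) 100 * sum(freq[c("G", "C")]) / acgt else NA_real_
  sw <- sort(w, decreasing = TRUE)
  n50 <- sw[which(cumsum(as.numeric(sw)) >= sum(as.numeric(sw)) / 2)[1L]]
  structure(list(total_bp = sum(as.numeric(w)), gc_pct = gc,
                 n_scaffolds = length(w), max_len = max(w), min_len = min(w),
                 n50 = n50),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(paste0("assembly: %d scaffolds, %.0f bp, GC %.1f%%, ",
                     "N50 %d bp (min %d, max %d)\n"),
              x$n_scaffolds, x$total_bp, x$gc_pct, x$n50, x$min_len, x$max_len))
  invisible(x)
}

#' Parse gene models from GFF3
#'
#' Expects gene/mRNA/CDS features with 1-based inclusive coordinates. For
#' multi-isoform genes the isoform with the most CDS segments represents the
#' gene (ties broken by smallest mRNA id), so every gene contributes exactly
#' one intron count. Protein length is total CDS length / 3.
#'
#' @param gff3 Path to a GFF3 file.
#' @return data.frame: gene_id, scaffold_id, strand, start, end, n_exons,
#'   intron_count, protein_length.
#' @export
parse_gene_models <- function(gff3) {
  gr <- rtracklayer::import(gff3)
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  cds <- df[df$type == "CDS", , drop = FALSE]
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) stop("no gene features in ", gff3)
  if (any(is.na(cds$Parent)))
    stop("CDS feature without a Parent in ", gff3)
  orphan <- setdiff(unique(cds$Parent), mrna$ID)
  if (length(orphan))
    stop("CDS with unknown parent mRNA: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  n_cds <- table(cds$Parent)
  cds_bp <- tapply(cds$width, cds$Parent, sum)
  mrna$n_exons <- as.integer(n_cds[mrna$ID])
  mrna$cds_bp <- as.numeric(cds_bp[mrna$ID])
  mrna <- mrna[!is.na(mrna$n_exons), , drop = FALSE]
  # per gene, the isoform with the most CDS segments; ties -> smallest ID
  o <- order(xtfrm(factor(mrna$Parent)), -mrna$n_exons,
             xtfrm(factor(mrna$ID,
                          levels = sort(unique(mrna$ID), method = "radix"))),
             method = "radix")
  mrna <- mrna[o, , drop = FALSE]
  pick <- mrna[!duplicated(mrna$Parent), , drop = FALSE]
  i <- match(genes$ID, pick$Parent)
  out <- data.frame(
    gene_id = genes$ID,
    scaffold_id = as.character(genes$seqnames),
    strand = as.character(genes$strand),
    start = genes$start, end = genes$end,
    n_exons = pick$n_exons[i],
    intron_count = pick$n_exons[i] - 1L,
    protein_length = as.integer(floor(pick$cds_bp[i] / 3)),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default intron-contrast grouping of donor classes
#'
#' Groups assignments into `eukaryote-like` (eukaryote best hits and
#' ORFans), `bacteria/archaea`, `giant virus`, and `other` (non-giant
#' viruses, unclassified).
#'
#' @param a An `lst_assignments` data.frame.
#' @return Character vector of group labels, one per row.
#' @export
default_intron_grouping <- function(a) {
  g <- rep("other", nrow(a))
  g[a$status == "ORFan"] <- "eukaryote-like"
  g[!is.na(a$superkingdom) & a$superkingdom == "Eukaryota"] <- "eukaryote-like"
  g[!is.na(a$superkingdom) &
      a$superkingdom %in% c("Bacteria", "Archaea")] <- "bacteria/archaea"
  g[!is.na(a$is_giant_virus) & a$is_giant_virus] <- "giant virus"
  g
}

#' Mean introns per gene by donor group
#'
#' @param models Gene models from [parse_gene_models()].
#' @param assignments An `lst_assignments` data.frame covering the models.
#' @param grouping Function mapping the assignment data.frame to group
#'   labels; default [default_intron_grouping()].
#' @return Named numeric vector of arithmetic mean introns per gene (full
#'   precision; round to one decimal for reporting). Empty groups are
#'   absent.
#' @export
mean_introns_by_group <- function(models, assignments,
                                  grouping = default_intron_grouping) {
  i <- match(models$gene_id, assignments$gene_id)
  if (anyNA(i))
    stop("gene models without assignments: ",
         paste(utils::head(models$gene_id[is.na(i)], 5), collapse = ", "))
  g <- grouping(assignments[i, , drop = FALSE])
  means <- tapply(models$intron_count, g, mean)
  out <- as.numeric(means)
  names(out) <- names(means)
  out[!is.na(out)]
}

#' Protein-length filter statistics
#'
#' @param models Gene models with `protein_length`.
#' @param min_aa Inclusive threshold in amino acids (default 100).
#' @return List: `count` of genes at or above the threshold, `proportion`
#'   as a one-decimal percentage ([pct()]), NA (with a warning) when there
#'   are no genes.
#' @export
length_filter_stats <- function(models, min_aa = 100L) {
  n <- nrow(models)
  cnt <- sum(models$protein_length >= min_aa)
  if (n == 0L) {
    warning("no gene models: proportion undefined")
    return(list(count = 0L, proportion = NA_real_))
  }
  list(count = cnt, proportion = pct(cnt, n))
}
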