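#' Ancestor of a taxon at a given rank
#'
#' Walks the lineage from the query toward the root and returns the taxid of
#' the first node with the requested rank; if the lineage carries no node of
#' that rank the query taxid itself is returned (leaves below species level
#' thus resolve to their species, species resolve to themselves).
#'
#' @param tree A `taxonomy_tree`.
#' @param taxid Taxon id.
#' @param rank Rank name (default "species").
#' @return Integer taxid.
#' @export
rank_ancestor <- function(tree, taxid, rank = "species") {
  lin <- lineage(tree, taxid)
  hit <- which(lin$rank == rank)
  if (length(hit)) lin$taxid[hit[[1L]]] else taxid
}

#' Flag suspected bacterial contaminant scaffolds
#'
#' A scaffold is excluded iff every gene on it is Assigned, every best hit is
#' bacterial, and all best-hit taxa share the same ancestor at `rank`
#' ("a totality of their genes best matching with the same bacteria").
#' Single-gene scaffolds satisfy "totality" literally and are excluded when
#' `min_genes = 1` (the default); raise `min_genes` to audit that choice.
#'
#' @param assignments An `lst_assignments` data.frame.
#' @param tree A `taxonomy_tree` (needed to resolve the rank ancestor).
#' @param rank Rank at which "same bacteria" is resolved (default species).
#' @param min_genes Minimum genes a scaffold must carry to be excludable.
#' @return data.frame of class `scaffold_verdicts`: scaffold_id, n_genes,
#'   verdict (kept/excluded), contaminant_taxid (NA when kept).
#' @export
flag_contaminants <- function(assignments, tree, rank = "species",
                              min_genes = 1L) {
  stopifnot(nrow(assignments) == 0L || !any(is.na(assignments$scaffold_id)))
  # resolve each distinct bacterial best-hit taxid once
  bact <- !is.na(assignments$superkingdom) &
    assignments$superkingdom == "Bacteria"
  anc <- rep(NA_integer_, nrow(assignments))
  if (any(bact)) {
    uniq <- unique(assignments$subject_taxid[bact])
    res <- vapply(uniq, function(t) {
      if (is.na(tree$idx[as.character(t)])) return(NA_integer_)
      rank_ancestor(tree, t, rank)
    }, integer(1))
    anc[bact] <- res[match(assignments$subject_taxid[bact], uniq)]
  }
  sc <- split(seq_len(nrow(assignments)), assignments$scaffold_id)
  verdicts <- lapply(names(sc), function(s) {
    i <- sc[[s]]
    all_bact <- all(assignments$status[i] == "Assigned") && all(bact[i])
    a <- unique(anc[i])
    excl <- all_bact && length(a) == 1L && !is.na(a) &&
      length(i) >= min_genes
    data.frame(scaffold_id = s, n_genes = length(i),
               verdict = if (excl) "excluded" else "kept",
               contaminant_taxid = if (excl) a else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, verdicts) %||%
    data.frame(scaffold_id = character(0), n_genes = integer(0),
               verdict = character(0), contaminant_taxid = integer(0))
  out <- out[order(out$scaffold_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scaffold_verdicts", "data.frame")
  out
}

#' Drop genes on excluded scaffolds
#'
#' @param assignments An `lst_assignments` data.frame.
#' @param verdicts Output of [flag_contaminants()]; must cover every
#'   scaffold present in `assignments`.
#' @return Assignments on kept scaffolds; the number of removed genes is
#'   attached as attribute `removed` and reported via `message()`.
#' @export
apply_verdicts <- function(assignments, verdicts) {
  miss <- setdiff(unique(assignments$scaffold_id), verdicts$scaffold_id)
  if (length(miss))
    stop("scaffolds without a verdict: ",
         paste(utils::head(miss, 5), collapse = ", "))
  excl <- verdicts$scaffold_id[verdicts$verdict == "excluded"]
  keep <- !(assignments$scaffold_id %in% excl)
  out <- assignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  removed <- sum(!keep)
  message("contamination filter: removed ", removed, " gene(s) on ",
          length(intersect(excl, assignments$scaffold_id)),
          " excluded scaffold(s); ", nrow(out), " gene(s) kept")
  if (nrow(out) == 0L && nrow(assignments) > 0L)
    warning("all scaffolds excluded: no genes remain")
  attr(out, "removed") <- removed
  out
}
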