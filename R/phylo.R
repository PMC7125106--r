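# normalize an alignment (named character vector, AAStringSet, or character
# matrix) to a character matrix with one row per sequence
as_char_matrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- aln
  } else {
    if (methods::is(aln, "XStringSet")) aln <- as.character(aln)
    if (!is.character(aln) || is.null(names(aln)))
      stop("alignment must be a named character vector, XStringSet or matrix")
    if (length(unique(nchar(aln))) != 1L)
      stop("aligned sequences must all have the same length")
    m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
    rownames(m) <- names(aln)
  }
  if (nrow(m) < 3L) stop("alignment must contain at least 3 sequences")
  if (anyDuplicated(rownames(m))) stop("duplicate sequence ids in alignment")
  m
}

#' Read an aligned FASTA of protein sequences
#'
#' @param path Aligned FASTA ('-' as gap).
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Uncorrected p-distance matrix from a protein alignment
#'
#' Pairwise deletion: for each pair, columns where either sequence has a
#' gap are dropped and the distance is mismatches / compared columns. A pair
#' with zero comparable columns gets distance 1.0 with a warning.
#'
#' @param aln Alignment (named character vector, `AAStringSet`, or
#'   character matrix).
#' @return Square symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(aln) {
  m <- as_char_matrix(aln)
  n <- nrow(m)
  gap <- m == "-"
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      nc <- sum(ok)
      if (nc == 0L) {
        warning("no comparable columns between ", rownames(m)[i], " and ",
                rownames(m)[j], "; distance set to 1")
        d <- 1
      } else {
        d <- sum(m[i, ok] != m[j, ok]) / nc
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

check_dist <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("distance matrix must be square")
  if (is.null(rownames(D))) stop("distance matrix must carry row names")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (any(D < 0)) stop("distances must be non-negative")
}

quote_label <- function(x) {
  ifelse(grepl("[^A-Za-z0-9_.-]", x), paste0("'", x, "'"), x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical NJ agglomeration (Q-matrix minimisation with the standard
#' branch-length formulas). Ties in Q are broken by the smallest (row,
#' column) index pair in the current matrix order, so the result is
#' deterministic under any consistent input ordering. Negative branch
#' lengths are clamped to 0 with the excess moved to the sibling edge (the
#' tip-to-tip path length is preserved).
#'
#' @param D Square symmetric distance matrix with >= 3 taxa.
#' @return Unrooted `phylo` tree (no support values).
#' @export
neighbor_joining <- function(D) {
  check_dist(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  frag <- quote_label(rownames(D))
  D <- unname(D)
  fmt <- function(x) sprintf("%.12g", x)
  clamp2 <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    qmin <- min(Q[upper.tri(Q)])
    cand <- which(upper.tri(Q) & Q == qmin, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    l <- clamp2(li, lj)
    newfrag <- paste0("(", frag[i], ":", fmt(l[1]), ",",
                      frag[j], ":", fmt(l[2]), ")")
    k <- setdiff(seq_len(n), c(i, j))
    dnew <- (D[i, k] + D[j, k] - D[i, j]) / 2
    D <- rbind(cbind(D[k, k, drop = FALSE], dnew), c(dnew, 0))
    frag <- c(frag[k], newfrag)
    n <- n - 1L
  }
  # three-point formulas for the final star resolution
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(max(la, 0)), ",",
                frag[2], ":", fmt(max(lb, 0)), ",",
                frag[3], ":", fmt(max(lc, 0)), ");")
  ape::read.tree(text = nwk)
}

#' Bootstrap support on a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal bipartition of the point-estimate
#' tree with its replicate frequency x 100 (stored in `node.label`).
#'
#' @param aln Alignment accepted by [p_distance()].
#' @param n_reps Number of replicates (>= 1; default 100).
#' @param seed Integer seed fixing the column-resampling stream.
#' @return Unrooted `phylo` with integer `node.label` supports in \[0, 100\].
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  m <- as_char_matrix(aln)
  point <- neighbor_joining(p_distance(m))
  reps <- vector("list", n_reps)
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    reps[[b]] <- suppressWarnings(
      neighbor_joining(p_distance(m[, cols, drop = FALSE])))
  }
  cnt <- ape::prop.clades(point, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  point$node.label <- as.character(round(100 * cnt / n_reps))
  point
}

#' Sister-clade congruence test for a candidate transfer
#'
#' Midpoint-roots the tree and asks whether the query leaf's sister clade
#' contains at least one putative-donor leaf and no outgroup leaf — the
#' topological question the transfer figures answer. This verdict rule is
#' this package's operationalisation (the source analyses color branches by
#' bootstrap without printing a fixed decision threshold).
#'
#' @param tree A `phylo` with branch lengths (e.g. from
#'   [bootstrap_support()]).
#' @param query_leaf Query tip label.
#' @param donor_leaves Character vector of donor tip labels.
#' @param outgroup_leaves Character vector of outgroup tip labels.
#' @return List: `verdict` ("supported"/"unsupported"), `sister_leaves`,
#'   and `support` (the subtending edge's bootstrap value, NA if the tree
#'   carries none).
#' @export
congruence_test <- function(tree, query_leaf, donor_leaves, outgroup_leaves) {
  tips <- tree$tip.label
  unknown <- setdiff(c(query_leaf, donor_leaves, outgroup_leaves), tips)
  if (length(unknown))
    stop("unknown leaf id(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(donor_leaves, outgroup_leaves)) ||
      query_leaf %in% c(donor_leaves, outgroup_leaves))
    stop("query, donor and outgroup leaves must be disjoint")
  rooted <- phangorn::midpoint(tree)
  tip <- which(rooted$tip.label == query_leaf)
  parent <- rooted$edge[rooted$edge[, 2] == tip, 1L]
  desc <- phangorn::Descendants(rooted, parent, type = "tips")[[1L]]
  sister <- rooted$tip.label[setdiff(desc, tip)]
  supported <- any(sister %in% donor_leaves) &&
    !any(sister %in% outgroup_leaves)
  supp <- NA_real_
  if (!is.null(rooted$node.label)) {
    lab <- rooted$node.label[parent - ape::Ntip(rooted)]
    supp <- suppressWarnings(as.numeric(lab))
  }
  list(verdict = if (supported) "supported" else "unsupported",
       sister_leaves = sister, support = supp)
}
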