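#' Load a taxonomy tree from node and name tables
#'
#' Reads a reduced taxonomy dump: a tab-separated node table with columns
#' `(taxid, parent, rank)` and a name table with columns `(taxid, name)`.
#' The root is the unique node that is its own parent. Ranks come from the
#' closed vocabulary `superkingdom, phylum, class, order, family, genus,
#' species, no_rank`.
#'
#' @param node_table Path to the node table (no header, tab-separated).
#' @param name_table Path to the name table (no header, tab-separated).
#' @return An object of class `taxonomy_tree`: a list with elements
#'   `nodes` (data.frame with taxid, parent, rank, name) and `root`.
#' @export
load_taxonomy <- function(node_table, name_table) {
  nodes <- utils::read.delim(node_table, header = FALSE,
                             col.names = c("taxid", "parent", "rank"),
                             colClasses = c("integer", "integer", "character"),
                             comment.char = "#", quote = "")
  nms <- utils::read.delim(name_table, header = FALSE,
                           col.names = c("taxid", "name"),
                           colClasses = c("integer", "character"),
                           comment.char = "#", quote = "")
  if (anyDuplicated(nodes$taxid))
    stop("duplicate taxid in node table: ",
         paste(unique(nodes$taxid[duplicated(nodes$taxid)]), collapse = ", "))
  ranks <- c("superkingdom", "phylum", "class", "order", "family",
             "genus", "species", "no_rank")
  bad <- setdiff(unique(nodes$rank), ranks)
  if (length(bad))
    stop("rank outside the controlled vocabulary: ", paste(bad, collapse = ", "))
  missing_parent <- setdiff(nodes$parent, nodes$taxid)
  if (length(missing_parent))
    stop("parent taxid absent from node table: ",
         paste(missing_parent, collapse = ", "))
  root <- nodes$taxid[nodes$taxid == nodes$parent]
  if (length(root) == 0L) stop("missing root (no self-parented node)")
  if (length(root) > 1L)
    stop("multiple self-parented nodes: ", paste(root, collapse = ", "))
  nodes$name <- nms$name[match(nodes$taxid, nms$taxid)]
  nodes$name[is.na(nodes$name)] <- ""
  tree <- structure(
    list(nodes = nodes, root = root,
         parent_of = stats::setNames(nodes$parent, nodes$taxid),
         idx = stats::setNames(seq_len(nrow(nodes)), nodes$taxid)),
    class = "taxonomy_tree")
  # cycle check doubles as the <= 64-step lineage invariant
  for (t in nodes$taxid) lineage_taxids(tree, t)
  tree
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", nrow(x$nodes), "nodes, root taxid", x$root, "\n")
  invisible(x)
}

#' Write a taxonomy tree back to node/name tables
#'
#' Inverse of [load_taxonomy()]; used to materialise synthetic taxonomies.
#'
#' @param tree A `taxonomy_tree`.
#' @param node_table,name_table Output paths.
#' @export
write_taxonomy <- function(tree, node_table, name_table) {
  n <- tree$nodes
  utils::write.table(n[, c("taxid", "parent", "rank")], node_table,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(n[, c("taxid", "name")], name_table,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(node_table, name_table))
}

# taxid path from node to root; errors on unknown taxid or on a walk that
# fails to reach the root within 64 steps (cycle or malformed tree)
lineage_taxids <- function(tree, taxid) {
  key <- as.character(taxid)
  if (is.na(tree$idx[key])) stop("unknown taxid: ", taxid)
  path <- integer(0)
  cur <- taxid
  for (step in seq_len(65L)) {
    path <- c(path, cur)
    if (cur == tree$root) return(path)
    cur <- unname(tree$parent_of[as.character(cur)])
  }
  stop("lineage of taxid ", taxid, " does not reach the root in 64 steps ",
       "(cycle detected)")
}

#' Lineage of a taxon
#'
#' @param tree A `taxonomy_tree`.
#' @param taxid Taxon id present in the tree.
#' @return data.frame of nodes ordered from the query taxon up to the root.
#' @export
lineage <- function(tree, taxid) {
  path <- lineage_taxids(tree, taxid)
  tree$nodes[tree$idx[as.character(path)], , drop = FALSE]
}

#' Load a donor-group marker configuration
#'
#' The donor-group scheme (which lineage names flag Amoebozoa, the bacterial
#' phyla, the CPR groups, the giant-virus lineages) is configuration, not
#' code. The file is tab-separated with header
#' `marker  subgroup  is_cpr  is_giant_virus`.
#'
#' @param path Config path; default is the scheme shipped with the package.
#' @return data.frame with those four columns.
#' @export
load_group_config <- function(path = default_group_config()) {
  cfg <- utils::read.delim(path, header = TRUE, colClasses =
                             c("character", "character", "logical", "logical"),
                           comment.char = "#", quote = "")
  need <- c("marker", "subgroup", "is_cpr", "is_giant_virus")
  if (!all(need %in% names(cfg)))
    stop("group config must have columns: ", paste(need, collapse = ", "))
  if (any(cfg$is_cpr & cfg$is_giant_virus))
    stop("a marker cannot be both CPR and giant virus")
  cfg
}

#' @rdname load_group_config
#' @export
default_group_config <- function() {
  system.file("extdata", "donor_groups.tsv", package = "lstscreen",
              mustWork = TRUE)
}

SUPERKINGDOMS <- c("Eukaryota", "Bacteria", "Archaea", "Viruses")

unclassified_group <- function() {
  data.frame(superkingdom = "Unclassified", subgroup = "",
             is_cpr = FALSE, is_giant_virus = FALSE,
             stringsAsFactors = FALSE)
}

#' Classify a taxon into the donor-group scheme
#'
#' Walks the lineage of `taxid`. The superkingdom is the lineage node named
#' Eukaryota/Bacteria/Archaea/Viruses; the subgroup is the most specific
#' configured marker found on the lineage (closest to the query). Lineages
#' with a superkingdom but no marker fall back to `Other-<superkingdom>`.
#' Taxa absent from the tree classify as Unclassified with a warning rather
#' than aborting, because hit tables routinely carry stale taxon ids.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxid Taxon id.
#' @param config Marker config from [load_group_config()].
#' @return One-row data.frame: superkingdom, subgroup, is_cpr, is_giant_virus.
#' @export
classify_taxid <- function(tree, taxid, config = load_group_config()) {
  if (is.na(taxid) || is.na(tree$idx[as.character(taxid)])) {
    warning("taxid ", taxid, " absent from taxonomy; classified Unclassified")
    return(unclassified_group())
  }
  lin <- lineage(tree, taxid)       # query ... root
  sk <- lin$name[lin$name %in% SUPERKINGDOMS]
  if (length(sk) == 0L) return(unclassified_group())
  sk <- sk[[1L]]
  hit <- match(lin$name, config$marker)       # first non-NA = most specific
  hit <- hit[!is.na(hit)]
  if (length(hit)) {
    m <- config[hit[[1L]], ]
    # flags only valid under their superkingdom (e.g. a name collision
    # between a virus marker and a bacterial clade must not set is_cpr)
    if (m$is_cpr && sk != "Bacteria") m$is_cpr <- FALSE
    if (m$is_giant_virus && sk != "Viruses") m$is_giant_virus <- FALSE
    out <- data.frame(superkingdom = sk, subgroup = m$subgroup,
                      is_cpr = m$is_cpr, is_giant_virus = m$is_giant_virus,
                      stringsAsFactors = FALSE)
  } else {
    other <- c(Eukaryota = "Other-eukaryote", Bacteria = "Other-bacteria",
               Archaea = "Other-archaea", Viruses = "Other-virus")
    out <- data.frame(superkingdom = sk, subgroup = unname(other[sk]),
                      is_cpr = FALSE, is_giant_virus = FALSE,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Vectorised donor-group classification with per-taxid caching
#'
#' @inheritParams classify_taxid
#' @param taxids Integer vector (NAs allowed; they classify Unclassified).
#' @return data.frame with one row per input taxid.
#' @export
classify_taxa <- function(tree, taxids, config = load_group_config()) {
  uniq <- unique(taxids)
  cache <- do.call(rbind, lapply(uniq, function(t)
    classify_taxid(tree, t, config)))
  cache[match(taxids, uniq), , drop = FALSE]
}
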