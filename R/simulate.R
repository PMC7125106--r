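#' Simulation configuration
#'
#' The defaults are the package's reference world: origin-class
#' proportions echoing the published taxonomic distribution (about 56%
#' eukaryote of which 19.8% Amoebozoa, 10.2% bacteria with a 1.3% CPR share
#' of the bacterial fraction, 0.6% archaea, 0.8% virus, 32.1% ORFan),
#' Poisson intron counts with class means 3.5 / 2.7 / 1.4 (contaminant
#' bacterial genes: 0 introns in expectation - they are prokaryotic DNA),
#' and zero-inflated Poisson read counts.
#'
#' @param seed Mandatory integer seed; every downstream draw is fixed by it.
#' @param n_scaffolds Number of non-contaminant scaffolds.
#' @param genes_per_scaffold_mean Mean genes per scaffold (>= 1; genes per
#'   scaffold are 1 + Poisson(mean - 1)).
#' @param origin_proportions Named vector over origin classes `orfan,
#'   eukaryote, amoebozoa, bacteria, cpr, archaea, giant_virus, other_virus,
#'   unclassified`; must sum to 1 (tolerance 1e-9).
#' @param noise_eps Probability that a fabricated best hit points to the
#'   wrong superkingdom.
#' @param n_contaminant_scaffolds,contaminant_genes Planted contaminant
#'   scaffolds (all genes best-matching one bacterial species) and genes on
#'   each.
#' @param intron_means Named per-class Poisson means (must cover every
#'   origin class plus `contaminant`).
#' @param counts_model List with `p_zero` (zero-inflation probability) and
#'   `lambda` (Poisson mean of the expressed component).
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(
    seed,
    n_scaffolds = 700L,
    genes_per_scaffold_mean = 1.5,
    origin_proportions = c(orfan = 0.321, eukaryote = 0.361,
                           amoebozoa = 0.198, bacteria = 0.1007,
                           cpr = 0.0013, archaea = 0.006,
                           giant_virus = 0.0079, other_virus = 0.0001,
                           unclassified = 0.004),
    noise_eps = 0,
    n_contaminant_scaffolds = 3L,
    contaminant_genes = 4L,
    intron_means = c(orfan = 3.5, eukaryote = 3.5, amoebozoa = 3.5,
                     bacteria = 2.7, cpr = 2.7, archaea = 2.7,
                     giant_virus = 1.4, other_virus = 1.4,
                     unclassified = 3.5, contaminant = 0),
    counts_model = list(p_zero = 0.5, lambda = 12)) {
  if (missing(seed)) stop("seed is mandatory")
  classes <- c("orfan", "eukaryote", "amoebozoa", "bacteria", "cpr",
               "archaea", "giant_virus", "other_virus", "unclassified")
  if (!setequal(names(origin_proportions), classes))
    stop("origin_proportions must be named over: ",
         paste(classes, collapse = ", "))
  if (any(origin_proportions < 0) ||
      abs(sum(origin_proportions) - 1) > 1e-9)
    stop("infeasible proportions: must be non-negative and sum to 1")
  if (!all(c(classes, "contaminant") %in% names(intron_means)) ||
      any(intron_means < 0))
    stop("intron_means must cover every class and be non-negative")
  stopifnot(noise_eps >= 0, noise_eps <= 1, genes_per_scaffold_mean >= 1,
            counts_model$p_zero >= 0, counts_model$p_zero <= 1,
            counts_model$lambda >= 0)
  structure(list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
                 genes_per_scaffold_mean = genes_per_scaffold_mean,
                 origin_proportions = origin_proportions[classes],
                 noise_eps = noise_eps,
                 n_contaminant_scaffolds = as.integer(n_contaminant_scaffolds),
                 contaminant_genes = as.integer(contaminant_genes),
                 intron_means = intron_means,
                 counts_model = counts_model),
            class = "sim_config")
}

# uniform draw from the wrong-superkingdom leaf pools
wrong_superkingdom_pool <- function(pools, class) {
  sk_of <- list(eukaryote = "Eukaryota", amoebozoa = "Eukaryota",
                bacteria = "Bacteria", cpr = "Bacteria",
                archaea = "Archaea",
                giant_virus = "Viruses", other_virus = "Viruses",
                unclassified = "", contaminant = "Bacteria")
  pool_sk <- list(Eukaryota = c(pools$eukaryote, pools$amoebozoa),
                  Bacteria = c(pools$bacteria, pools$cpr),
                  Archaea = pools$archaea,
                  Viruses = c(pools$giant_virus, pools$other_virus))
  unlist(pool_sk[setdiff(names(pool_sk), sk_of[[class]])], use.names = FALSE)
}

#' Generate a full synthetic input bundle with planted truth
#'
#' Writes every input the screening pipeline needs - taxonomy node/name
#' tables, scaffold FASTA, GFF3 gene models, a 13-column hit table, a
#' counts TSV - plus the planted-truth table, all deterministic given the
#' config seed. Each non-ORFan gene receives 1-20 hits with the planted
#' donor as surviving-bitscore argmax with probability `1 - noise_eps`;
#' self-hits (outscoring everything, removed by self-taxon exclusion) and
#' above-threshold decoys (outscoring everything, removed by the e-value
#' filter) are planted so both filters are exercised. Contaminant scaffolds
#' satisfy the exclusion rule by construction.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return List: `paths` (named file paths), `truth` (data.frame gene_id,
#'   scaffold_id, origin_class, donor_taxid, is_contaminant, intron_count,
#'   read_count), `catalog`, `scaffold_lengths`, `self_taxid`, `config`.
#' @export
simulate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  tax <- synthetic_taxonomy()
  pools <- synthetic_donor_pools()
  paths <- vapply(c(nodes = "nodes.tsv", names = "names.tsv",
                    fasta = "genome.fasta", gff3 = "genes.gff3",
                    hits = "hits.tsv", counts = "counts.tsv",
                    truth = "truth.tsv"),
                  function(f) file.path(dir, f), character(1))
  write_taxonomy(tax, paths[["nodes"]], paths[["names"]])

  # --- scaffold and gene skeleton -------------------------------------
  gps <- 1L + stats::rpois(config$n_scaffolds,
                           config$genes_per_scaffold_mean - 1)
  n_scf <- config$n_scaffolds + config$n_contaminant_scaffolds
  gps <- c(gps, rep(config$contaminant_genes,
                    config$n_contaminant_scaffolds))
  scf_ids <- sprintf("scf%05d", seq_len(n_scf))
  is_cont_scf <- c(rep(FALSE, config$n_scaffolds),
                   rep(TRUE, config$n_contaminant_scaffolds))
  N <- sum(gps)
  gene_scf <- rep(scf_ids, gps)
  gene_cont <- rep(is_cont_scf, gps)
  gene_id <- sprintf("g%06d", seq_len(N))

  # --- planted origins -------------------------------------------------
  cls <- character(N)
  cls[!gene_cont] <- sample(names(config$origin_proportions),
                            sum(!gene_cont), replace = TRUE,
                            prob = config$origin_proportions)
  cls[gene_cont] <- "contaminant"
  gidx <- split(seq_len(N), factor(gene_scf, levels = scf_ids))
  # Planted transfers sit embedded among amoebal genes (the biological
  # situation the screen targets), so planted contaminant scaffolds must be
  # the ONLY scaffolds that are entirely bacterial-matching. Repair by
  # swapping class labels between genes, which preserves the marginal
  # origin-class counts exactly.
  bact_cls <- c("bacteria", "cpr")
  nonbact <- !(cls %in% c(bact_cls, "contaminant"))
  nb_by_scf <- vapply(gidx, function(i) sum(nonbact[i]), integer(1))
  viol <- which(vapply(seq_along(gidx), function(s)
    !is_cont_scf[s] && all(cls[gidx[[s]]] %in% bact_cls), logical(1)))
  for (s in viol) {
    i <- gidx[[s]][1L]
    ds <- which(nb_by_scf >= 2L)
    ds <- ds[ds != s]
    if (length(ds) == 0L)
      stop("infeasible proportions: cannot embed transfers among host genes")
    ds <- ds[1L]
    j <- gidx[[ds]][which(nonbact[gidx[[ds]]])[1L]]
    tmp <- cls[i]; cls[i] <- cls[j]; cls[j] <- tmp
    nonbact[i] <- TRUE; nonbact[j] <- FALSE
    nb_by_scf[ds] <- nb_by_scf[ds] - 1L
    nb_by_scf[s] <- nb_by_scf[s] + 1L
  }
  donor <- rep(NA_integer_, N)
  for (k in setdiff(unique(cls), c("orfan", "contaminant")))
    donor[cls == k] <- sample(rep(pools[[k]], 2), sum(cls == k),
                              replace = TRUE)
  # one bacterial species per contaminant scaffold, shared by all its genes
  cont_species <- sample(rep(pools$bacteria, 2),
                         config$n_contaminant_scaffolds)
  if (config$n_contaminant_scaffolds > 0) {
    cont_map <- stats::setNames(cont_species,
                                scf_ids[is_cont_scf])
    donor[gene_cont] <- cont_map[gene_scf[gene_cont]]
  }

  # --- gene structure --------------------------------------------------
  introns <- stats::rpois(N, config$intron_means[cls])
  aa <- pmax(50L, as.integer(round(stats::rlnorm(N, log(230), 0.6))))
  cds_bp <- 3L * aa
  n_ex <- introns + 1L

  # --- layout, GFF3 and FASTA ------------------------------------------
  gff <- character(0)
  fasta_seqs <- character(n_scf)
  scf_len <- integer(n_scf)
  gene_start <- integer(N); gene_end <- integer(N)
  strand <- sample(c("+", "-"), N, replace = TRUE)
  gff_list <- vector("list", n_scf)
  for (s in seq_len(n_scf)) {
    pos <- 1L
    rows <- character(0)
    for (g in gidx[[s]]) {
      pos <- pos + sample(100:300, 1L)
      k <- n_ex[g]
      ex <- rep(cds_bp[g] %/% k, k)
      rem <- cds_bp[g] - sum(ex)
      if (rem > 0) ex[seq_len(rem)] <- ex[seq_len(rem)] + 1L
      intr <- if (k > 1L) sample(60:200, k - 1L, replace = TRUE) else integer(0)
      starts <- pos + cumsum(c(0L, ex[-k] + intr))
      ends <- starts + ex - 1L
      gene_start[g] <- pos; gene_end[g] <- ends[k]
      gid <- gene_id[g]; mid <- paste0(gid, ".t1")
      rows <- c(rows,
                sprintf("%s\tlstsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        scf_ids[s], pos, ends[k], strand[g], gid),
                sprintf("%s\tlstsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                        scf_ids[s], pos, ends[k], strand[g], mid, gid),
                sprintf("%s\tlstsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                        scf_ids[s], starts, ends, strand[g], mid, mid))
      pos <- ends[k]
    }
    scf_len[s] <- pos + sample(100:300, 1L)
    gff_list[[s]] <- rows
    fasta_seqs[s] <- paste(sample(c("A", "C", "G", "T"), scf_len[s],
                                  replace = TRUE,
                                  prob = c(0.2915, 0.2085, 0.2085, 0.2915)),
                           collapse = "")
  }
  writeLines(c("##gff-version 3", unlist(gff_list)), paths[["gff3"]])
  seqset <- Biostrings::DNAStringSet(fasta_seqs)
  names(seqset) <- scf_ids
  Biostrings::writeXStringSet(seqset, paths[["fasta"]], width = 80L)

  # --- hit table -------------------------------------------------------
  self <- pools$self
  all_leaves <- unlist(pools[setdiff(names(pools), "self")],
                       use.names = FALSE)
  hit_rows <- vector("list", N)
  acc <- 0L
  fmt_row <- function(q, taxid, bit, ev, n) {
    acc_ids <- sprintf("ACC%07d", acc + seq_len(n))
    acc <<- acc + n
    sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f\t%d",
            q, acc_ids, stats::runif(n, 25, 95),
            sample(80:600, n, replace = TRUE),
            sample(1:80, n, replace = TRUE),
            sample(0:5, n, replace = TRUE),
            rep(1L, n), sample(80:600, n, replace = TRUE),
            rep(1L, n), sample(80:600, n, replace = TRUE),
            formatC(ev, format = "e", digits = 3), bit, taxid)
  }
  for (g in seq_len(N)) {
    if (cls[g] == "orfan") next
    n_hits <- sample(1:20, 1L)
    best_bit <- round(stats::runif(1, 180, 400), 1)
    best_taxid <- donor[g]
    if (cls[g] != "contaminant" && config$noise_eps > 0 &&
        stats::runif(1) < config$noise_eps) {
      wp <- wrong_superkingdom_pool(pools, cls[g])
      best_taxid <- sample(rep(wp, 2), 1L)
    }
    ev_of <- function(bit) pmin(9.9e-4, exp(-bit / 4) *
                                  10^stats::runif(length(bit), -0.5, 0.5))
    rows <- fmt_row(gene_id[g], best_taxid, best_bit, ev_of(best_bit), 1L)
    if (n_hits > 1L) {
      bits <- round(stats::runif(n_hits - 1L, 50, best_bit - 5), 1)
      taxids <- sample(rep(all_leaves, 2), n_hits - 1L, replace = TRUE)
      rows <- c(rows, fmt_row(gene_id[g], taxids, bits, ev_of(bits),
                              n_hits - 1L))
    }
    if (stats::runif(1) < 0.5)   # self-hit: outscores all, filtered by taxid
      rows <- c(rows, fmt_row(gene_id[g], self, best_bit + 100,
                              1e-30, 1L))
    if (stats::runif(1) < 0.3)   # decoy above the e-value threshold
      rows <- c(rows, fmt_row(gene_id[g],
                              sample(rep(all_leaves, 2), 1L),
                              best_bit + 50, 10^stats::runif(1, -2.2, 0),
                              1L))
    hit_rows[[g]] <- rows
  }
  writeLines(c("# synthetic hit table: 12 standard columns + subject taxid",
               unlist(hit_rows)), paths[["hits"]])

  # --- read counts -----------------------------------------------------
  zero <- stats::runif(N) < config$counts_model$p_zero
  rc <- ifelse(zero, 0L, stats::rpois(N, config$counts_model$lambda))
  in_file <- rc > 0L | stats::runif(N) > 0.05  # some zero rows omitted
  counts_lines <- sprintf("%s\t%d", gene_id[in_file], rc[in_file])
  counts_lines <- c(counts_lines,
                    sprintf("__no_feature\t%d", sample(1000:5000, 1L)),
                    sprintf("__ambiguous\t%d", sample(100:500, 1L)))
  writeLines(counts_lines, paths[["counts"]])

  # --- truth -----------------------------------------------------------
  truth <- data.frame(gene_id = gene_id, scaffold_id = gene_scf,
                      origin_class = cls, donor_taxid = donor,
                      is_contaminant = gene_cont, intron_count = introns,
                      read_count = rc, stringsAsFactors = FALSE)
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  list(paths = as.list(paths), truth = truth,
       catalog = data.frame(gene_id = gene_id, scaffold_id = gene_scf,
                            stringsAsFactors = FALSE),
       scaffold_lengths = stats::setNames(scf_len, scf_ids),
       self_taxid = self, config = config)
}

#' Simulate a protein alignment along a tree
#'
#' Independent-site substitution: the root sequence is uniform over the 20
#' amino acids; along each edge every site substitutes with probability
#' `1 - exp(-rate * edge_length)` to a uniformly chosen different residue.
#' Expected pairwise p-distance therefore increases with path length. No
#' gaps are introduced.
#'
#' @param tree A `phylo` (or newick string); missing edge lengths default
#'   to 1.
#' @param n_columns Alignment length (>= 50 for distance estimates worth
#'   using; shorter values are allowed for toy cases).
#' @param rate Substitution rate, in (0, 0.75).
#' @param seed Integer seed.
#' @return Named character vector: one aligned sequence per tip.
#' @export
simulate_alignment <- function(tree, n_columns = 200L, rate = 0.1,
                               seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(rate > 0, rate < 0.75, n_columns >= 1)
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  el <- tree$edge.length %||% rep(1, nrow(tree$edge))
  seqs <- vector("list", ntip + nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample(aa, n_columns, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    len <- if (is.null(tree$edge.length)) 1 else
      ord$edge.length[e]
    p <- 1 - exp(-rate * len)
    s <- seqs[[par]]
    mut <- which(stats::runif(n_columns) < p)
    if (length(mut)) {
      cur <- s[mut]
      repl <- sample(aa, length(mut), replace = TRUE)
      clash <- repl == cur
      while (any(clash)) {
        repl[clash] <- sample(aa, sum(clash), replace = TRUE)
        clash <- repl == cur
      }
      s[mut] <- repl
    }
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  stats::setNames(out, tree$tip.label)
}
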