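test_that("p_distance matches closed forms and a brute-force oracle", {
  a <- c(s1 = "AAAA", s2 = "AAAA", s3 = "AATT")
  D <- p_distance(a)
  expect_equal(D["s1", "s2"], 0)
  expect_equal(D["s1", "s3"], 0.5)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))

  # pairwise deletion of gapped columns
  g <- c(s1 = "AC-T", s2 = "A--T", s3 = "ACGT")
  Dg <- p_distance(g)
  expect_equal(Dg["s1", "s2"], 0)      # 3 comparable columns, 0 mismatches
  expect_equal(Dg["s1", "s3"], 0)      # gap column dropped
  expect_warning(Dz <- p_distance(c(a = "--X", b = "XX-", c = "XXX")),
                 "no comparable")
  expect_equal(Dz["a", "b"], 1)

  set.seed(3)
  aa <- c(LETTERS[1:20], "-")
  for (rep in 1:5) {
    m <- matrix(sample(aa, 8 * 60, TRUE), nrow = 8,
                dimnames = list(paste0("t", 1:8), NULL))
    D <- p_distance(m)
    for (i in 1:7) for (j in (i + 1):8) {       # column-by-column oracle
      cmp <- 0; mis <- 0
      for (k in 1:60) {
        if (m[i, k] != "-" && m[j, k] != "-") {
          cmp <- cmp + 1
          if (m[i, k] != m[j, k]) mis <- mis + 1
        }
      }
      expect_equal(D[i, j], if (cmp == 0) 1 else mis / cmp)
    }
  }
})

test_that("neighbor_joining: three-point closed form", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_equal(ape::Ntip(tr), 3L)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (5 + 9 - 10) / 2)
  expect_equal(bl[["b"]], (5 + 10 - 9) / 2)
  expect_equal(bl[["c"]], (9 + 10 - 5) / 2)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
  Dbad <- D; Dbad[1, 2] <- 4
  expect_error(neighbor_joining(Dbad), "symmetric")
})

test_that("neighbor_joining recovers additive trees exactly", {
  # 4-taxon additive matrix from a known tree
  tr <- ape::read.tree(text = "((a:1,b:2):1.5,(c:1,d:3):0.5);")
  o <- c("a", "b", "c", "d")
  D <- ape::cophenetic.phylo(tr)[o, o]
  est <- neighbor_joining(D)
  expect_equal(ape::dist.topo(ape::unroot(tr), est), 0, ignore_attr = TRUE)
  expect_lt(max(abs(ape::cophenetic.phylo(est)[o, o] - D)), 1e-12)

  # 8-taxon path-length reconstruction within 1e-9
  ra <- rand_additive(8, seed = 81)
  est8 <- neighbor_joining(ra$D)
  o8 <- rownames(ra$D)
  expect_lt(max(abs(ape::cophenetic.phylo(est8)[o8, o8] - ra$D)), 1e-9)

  # random binary trees, topology recovery (subset; full 100 in acceptance)
  for (s in 1:15) {
    ra <- rand_additive(sample(4:10, 1), seed = 1000 + s)
    est <- neighbor_joining(ra$D)
    expect_equal(ape::dist.topo(ra$tree, est), 0, ignore_attr = TRUE)
  }
})

test_that("bootstrap_support is seed-deterministic with supports in [0,100]", {
  tree <- ape::read.tree(text =
    "(((a:0.1,b:0.1):1,(c:0.1,d:0.1):1):0.1,(e:0.3,f:0.4):0.2);")
  aln <- simulate_alignment(tree, n_columns = 120, rate = 0.2, seed = 5)
  b1 <- bootstrap_support(aln, n_reps = 30, seed = 11)
  b2 <- bootstrap_support(aln, n_reps = 30, seed = 11)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  sup <- as.numeric(b1$node.label)
  expect_true(all(sup >= 0 & sup <= 100))
  # single replicate forces supports into {0, 100}
  b3 <- bootstrap_support(aln, n_reps = 1, seed = 2)
  expect_true(all(as.numeric(b3$node.label) %in% c(0, 100)))
  # leaf-order permutation of the alignment leaves supports unchanged
  perm <- aln[c(4, 1, 6, 2, 5, 3)]
  b4 <- bootstrap_support(perm, n_reps = 30, seed = 11)
  key <- function(tr) {
    pp <- ape::prop.part(tr)
    sort(vapply(pp, function(p)
      paste(sort(attr(pp, "labels")[p]), collapse = ","), ""))
  }
  expect_identical(key(b1), key(b4))
})

test_that("separating edges of well-separated clades get high support", {
  tree <- ape::read.tree(text =
    "((a:0.05,b:0.05):2,(c:0.05,d:0.05):2);")
  aln <- simulate_alignment(tree, n_columns = 200, rate = 0.15, seed = 9)
  bt <- bootstrap_support(aln, n_reps = 100, seed = 4)
  # the a|b vs c|d bipartition is an internal edge of the point tree
  sup <- as.numeric(bt$node.label)
  expect_gte(max(sup, na.rm = TRUE), 95)
})

test_that("congruence_test answers the sister-clade question", {
  # query grafted inside the donor clade -> supported
  t1 <- ape::read.tree(text =
    "(((query:0.1,don1:0.1):0.2,don2:0.3):1,(out1:0.2,out2:0.2):1);")
  r1 <- congruence_test(t1, "query", c("don1", "don2"), c("out1", "out2"))
  expect_equal(r1$verdict, "supported")
  expect_equal(r1$sister_leaves, "don1")

  # query sister to the outgroup clade -> unsupported
  t2 <- ape::read.tree(text =
    "(((query:0.1,(out1:0.1,out2:0.1):0.2):0.2,don2:0.3):1,don1:1.4);")
  r2 <- congruence_test(t2, "query", c("don1", "don2"), c("out1", "out2"))
  expect_equal(r2$verdict, "unsupported")

  # minimal 3-leaf case decided by the unique internal edge
  t3 <- ape::read.tree(text = "(query:0.1,don:0.1,out:1.5);")
  r3 <- congruence_test(t3, "query", "don", "out")
  expect_equal(r3$verdict, "supported")

  expect_error(congruence_test(t3, "nope", "don", "out"), "unknown leaf")
  expect_error(congruence_test(t3, "query", "don", "don"), "disjoint")

  # invariant to re-rooting outside the query subtree
  t1r <- ape::root(t1, outgroup = "out1", resolve.root = TRUE)
  r1r <- congruence_test(t1r, "query", c("don1", "don2"), c("out1", "out2"))
  expect_equal(r1r$verdict, r1$verdict)
})
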