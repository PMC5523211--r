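test_that("NJ reproduces the classic additive 4-taxon example", {
  ids <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(ids, ids))
  tr <- neighbor_joining(D)
  # topology: (A,B) | (C,D)
  expect_identical(split_set(tr),
                   barcodegap:::split_key(c("C", "D"), ids))
  # path lengths reproduce the additive input exactly
  expect_equal(ape::cophenetic.phylo(tr)[ids, ids], D, tolerance = 1e-9)
  # tip branch lengths A:1 B:2 C:3 D:4, internal 1
  tip_len <- setNames(tr$edge.length[match(seq_len(4), tr$edge[, 2])],
                      tr$tip.label)
  expect_equal(tip_len[ids], c(A = 1, B = 2, C = 3, D = 4))
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(unname(internal), 1)
})

test_that("3-taxon NJ uses the three-point formulas", {
  ids <- c("a", "b", "c")
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3, dimnames = list(ids, ids))
  tr <- neighbor_joining(D)
  tip_len <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                      tr$tip.label)
  expect_equal(tip_len[ids], c(a = 0.1, b = 0.2, c = 0.4))
})

test_that("NJ recovers the split of a 2-cluster ultrametric matrix", {
  ids <- c("a1", "a2", "b1", "b2")
  D <- matrix(0.10, 4, 4, dimnames = list(ids, ids))
  diag(D) <- 0
  D["a1", "a2"] <- D["a2", "a1"] <- 0.01
  D["b1", "b2"] <- D["b2", "b1"] <- 0.01
  tr <- neighbor_joining(D)
  expect_identical(split_set(tr),
                   barcodegap:::split_key(c("b1", "b2"), ids))
  # exhaustive enumeration oracle agrees
  oracle <- ls_best_topology(D)
  expect_equal(phangorn::RF.dist(tr, oracle$tree), 0)
})

test_that("NJ matches the exhaustive least-squares oracle on additive input", {
  set.seed(202)
  for (n in c(4, 5)) {
    for (rep in 1:5) {
      ra <- rand_additive(n)
      tr <- neighbor_joining(ra$D)
      oracle <- ls_best_topology(ra$D)
      expect_lt(oracle$rss, 1e-18)
      expect_equal(phangorn::RF.dist(tr, oracle$tree), 0)
      expect_equal(ape::cophenetic.phylo(tr)[rownames(ra$D), colnames(ra$D)],
                   ra$D, tolerance = 1e-9)
    }
  }
})

test_that("NJ recovers random generating topologies up to n = 10", {
  set.seed(303)
  for (n in c(6, 8, 10)) {
    for (rep in 1:5) {
      ra <- rand_additive(n)
      tr <- neighbor_joining(ra$D)
      expect_equal(phangorn::RF.dist(tr, ra$tree), 0)
      # independent NJ implementation agrees on the topology
      expect_equal(phangorn::RF.dist(tr, ape::nj(ra$D)), 0)
    }
  }
})

test_that("NJ rejects undefined entries and tiny matrices", {
  D <- matrix(c(0, NA, NA, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(D), "at least 3")
  D3 <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D3) <- 0
  D3[1, 2] <- D3[2, 1] <- NA
  expect_error(neighbor_joining(D3), "undefined")
})

test_that("clamping negative branch lengths preserves path lengths through joins", {
  # a strongly non-additive matrix that produces a negative NJ branch
  ids <- letters[1:4]
  D <- matrix(c(0, 0.1, 0.4, 0.45,
                0.1, 0, 0.42, 0.47,
                0.4, 0.42, 0, 0.05,
                0.45, 0.47, 0.05, 0), 4, 4, dimnames = list(ids, ids))
  D[1, 2] <- D[2, 1] <- 0.6   # force distortion
  tr <- neighbor_joining(D, clamp_negative = TRUE)
  expect_true(all(tr$edge.length >= 0))
  # on additive input clamping is a no-op
  ra <- rand_additive(6)
  expect_equal(ape::cophenetic.phylo(neighbor_joining(ra$D, clamp_negative = TRUE)),
               ape::cophenetic.phylo(neighbor_joining(ra$D)))
})

cluster_alignment <- function() {
  # two clean 3-member clusters ~20% apart, identical within
  base <- strsplit(paste(rep("ACGT", 25), collapse = ""), "")[[1L]]
  other <- base
  flip <- seq(1, 100, 5)
  other[flip] <- chartr("ACGT", "CATG", other[flip])
  mat <- rbind(a1 = base, a2 = base, a3 = base,
               b1 = other, b2 = other, b3 = other)
  as_labeled(mat, species = c("A", "A", "A", "B", "B", "B"))
}

test_that("bootstrap gives 100% support to a clean cluster split and is reproducible", {
  aln <- cluster_alignment()
  tr1 <- bootstrap_supports(aln, replicates = 50, seed = 9)
  splits <- barcodegap:::tree_splits(tr1)
  key <- barcodegap:::split_key(c("b1", "b2", "b3"), tr1$tip.label)
  node <- as.integer(names(splits)[splits == key])
  expect_equal(tr1$node.label[node - 6L], "100")
  tr2 <- bootstrap_supports(aln, replicates = 50, seed = 9)
  expect_identical(tr1$node.label, tr2$node.label)
  sup <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
})

test_that("bootstrap supports are invariant to tip input order", {
  # intra_sub high enough that all sequences are pairwise distinct: identical
  # sequences are genuine NJ ties, where join order legitimately depends on
  # input order
  set.seed(77)
  sim <- simulate_barcodes(barcode_sim_config(n_species = 4,
    specimens_per_species = c(3, 2, 3, 2), L = 500, n_outgroups = 0,
    intra_sub = 0.05, inter_sub = 0.15, missing_end_prob = 0, seed = 77))
  aln <- sim$aln
  expect_false(any(duplicated(apply(aln$matrix, 1, paste, collapse = ""))))
  perm <- sample(nrow(aln$matrix))
  aln2 <- structure(list(matrix = aln$matrix[perm, , drop = FALSE],
                         records = aln$records[perm, , drop = FALSE]),
                    class = "labeled_alignment")
  t1 <- bootstrap_supports(aln, replicates = 30, seed = 5)
  t2 <- bootstrap_supports(aln2, replicates = 30, seed = 5)
  s1 <- barcodegap:::tree_splits(t1)
  s2 <- barcodegap:::tree_splits(t2)
  sup1 <- setNames(t1$node.label[as.integer(names(s1)) - length(t1$tip.label)], s1)
  sup2 <- setNames(t2$node.label[as.integer(names(s2)) - length(t2$tip.label)], s2)
  shared <- intersect(names(sup1), names(sup2))
  expect_identical(sort(names(sup1)), sort(names(sup2)))
  # same column resampling -> same supports split by split
  expect_identical(sup1[shared], sup2[shared])
})

test_that("Newick round-trips topology, lengths, and supports", {
  set.seed(11)
  ra <- rand_additive(7)
  tr <- neighbor_joining(ra$D)
  tr$node.label <- as.character(seq(50, 50 + tr$Nnode - 1))
  back <- ape::read.tree(text = write_newick(tr))
  expect_equal(phangorn::RF.dist(tr, back), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  expect_setequal(back$node.label, tr$node.label)
  # a support of 56 appears as a node label in the serialized form
  tr$node.label[2] <- "56"
  expect_match(write_newick(tr), ")56", fixed = TRUE)
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  expect_match(readLines(f)[1], ";$")
})

test_that("monophyly is read off tree bipartitions", {
  rec <- data.frame(seq_id = c("a1", "a2", "b1", "b2"),
                    species = c("A", "A", "B", "B"),
                    role = "ingroup", stringsAsFactors = FALSE)
  good <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  rep1 <- monophyly_report(good, rec)
  expect_true(all(rep1$monophyletic))
  bad <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  rep2 <- monophyly_report(bad, rec)
  expect_false(rep2$monophyletic[rep2$species == "A"])
  expect_false(rep2$monophyletic[rep2$species == "B"])
})

test_that("single-specimen species are monophyletic with NA support; ingroup split is reported", {
  rec <- data.frame(seq_id = c("a1", "a2", "p1", "o1", "o2"),
                    species = c("A", "A", "P", "Out", "Out"),
                    role = c("ingroup", "ingroup", "ingroup",
                             "outgroup", "outgroup"),
                    stringsAsFactors = FALSE)
  tr <- ape::read.tree(text = "(((a1:1,a2:1)90:1,p1:1)80:1,o1:1,o2:1);")
  rep <- monophyly_report(tr, rec)
  P <- rep[rep$species == "P", ]
  expect_true(P$monophyletic)
  expect_true(is.na(P$support))
  A <- rep[rep$species == "A", ]
  expect_true(A$monophyletic)
  expect_equal(A$support, 90)
  G <- rep[rep$species == "<ingroup>", ]
  expect_true(G$monophyletic)
  expect_equal(G$support, 80)
})
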