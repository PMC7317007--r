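# NJ inference, bipartitions, RF distances, bootstrap supports.

test_that("distance_matrix is symmetric, zero-diagonal and permutation-stable", {
  const <- dna_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC"))
  expect_true(all(distance_matrix(const) == 0))

  aln <- random_alignment(4, 200, seed = 12)
  # unrelated rows saturate some pairs: the imputation path still must
  # return a symmetric, permutation-stable matrix
  D <- suppressWarnings(distance_matrix(aln))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 4))
  perm <- unclass(aln)[c(3, 1, 4, 2), ]
  D2 <- suppressWarnings(distance_matrix(dna_alignment(perm)))
  expect_equal(D2[rownames(D), colnames(D)], D)

  nogap <- dna_alignment(c(a = "AC--", b = "ACGT", c = "--GT"))
  expect_error(distance_matrix(nogap), "no comparable")
})

test_that("NJ recovers additive matrices exactly, including the 3-taxon formulas", {
  ref <- read_newick("((A:1,B:2):1,(C:3,D:4):1);")
  D <- ape::cophenetic.phylo(ref)
  tr <- nj_tree(D)
  expect_equal(rf_distance(tr, ref), 0L)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D)

  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  expect_equal(t3$Nnode, 1L)
  lens <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 2, C = 3))

  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2)), "at least 3")
  d3b <- d3; d3b[1, 2] <- d3b[2, 1] <- Inf
  expect_error(nj_tree(d3b), "non-finite")
})

test_that("NJ recovers random additive and ultrametric topologies", {
  for (seed in 1:30) {
    n <- withr::with_seed(seed, sample(5:12, 1))
    tr <- simulate_tree(n, seed = 200 + seed)
    D <- ape::cophenetic.phylo(tr)
    expect_equal(rf_distance(nj_tree(D), tr), 0L, info = paste("seed", seed))
  }
  for (seed in 1:10) {
    tr <- withr::with_seed(300 + seed, ape::rcoal(6))
    expect_equal(rf_distance(nj_tree(ape::cophenetic.phylo(tr)), tr), 0L)
  }
})

test_that("negative NJ branch lengths are clamped with the deficit moved to the sibling", {
  # a non-additive matrix known to produce a negative NJ edge
  D <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D[1, 2] <- D[2, 1] <- 0.1  # distort
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  raw <- ape::nj(D)
  expect_equal(sum(tr$edge.length), sum(raw$edge.length))
})

test_that("RF distance counts split symmetric differences and is a metric", {
  t1 <- read_newick("((A,B),(C,D));")
  t2 <- read_newick("((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  expect_error(rf_distance(t1, read_newick("((A,B),(C,E));")), "leaf sets")

  # maximum 2(n-3) between fully resolved 6-leaf trees; phangorn cross-check
  trees <- withr::with_seed(41, lapply(1:12, function(i) ape::rtree(6, br = NULL)))
  for (i in 1:11) {
    for (j in (i + 1):12) {
      mine <- rf_distance(trees[[i]], trees[[j]])
      ref <- phangorn::RF.dist(trees[[i]], trees[[j]])
      expect_equal(mine, as.integer(ref))
      expect_lte(mine, 2L * (6L - 3L))
    }
  }
  # triangle inequality spot-check
  for (k in 1:10) {
    ijk <- withr::with_seed(k, sample(12, 3))
    expect_lte(rf_distance(trees[[ijk[1]]], trees[[ijk[3]]]),
               rf_distance(trees[[ijk[1]]], trees[[ijk[2]]]) +
                 rf_distance(trees[[ijk[2]]], trees[[ijk[3]]]))
  }
})

clean_split_alignment <- function() {
  # 20 copies of the site pattern (A,A,C,C) + invariant padding (keeps
  # transversion proportions inside the K80 domain)
  m <- rbind(A = rep(c("A", "G"), c(20, 80)),
             B = rep(c("A", "G"), c(20, 80)),
             C = rep(c("C", "G"), c(20, 80)),
             D = rep(c("C", "G"), c(20, 80)))
  dna_alignment(m)
}

test_that("bootstrap gives full support to a clean split and is seed-deterministic", {
  aln <- clean_split_alignment()
  tr <- bootstrap_support(aln, B = 50, seed = 3)
  expect_equal(mean_support(tr), 100)
  bip <- tree_bipartitions(tr)
  expect_equal(bip$key, "C;D")

  tr2 <- bootstrap_support(aln, B = 50, seed = 3)
  expect_equal(write_newick(tr2), write_newick(tr))

  noisy <- simulate_alignment(simulation_config(
    n_taxa = 6,
    marker_plan = tibble::tibble(name = "m", class = "cpCDS",
                                 length = 150L, rate = 1),
    seed = 8))$alignment
  a <- bootstrap_support(noisy, B = 20, seed = 1)
  b <- bootstrap_support(noisy, B = 20, seed = 1)
  expect_identical(a$node.label, b$node.label)

  one <- bootstrap_support(noisy, B = 1, seed = 5)
  sup <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
})

test_that("bootstrap supports converge on strong simulated signal", {
  # balanced tree with every internal edge at 0.05 subst/site: ~200
  # expected substitutions per edge over 4 kb, i.e. strong signal
  strong <- paste0("(((t1:0.05,t2:0.05):0.05,(t3:0.05,t4:0.05):0.05):0.05,",
                   "((t5:0.05,t6:0.05):0.05,(t7:0.05,t8:0.05):0.05):0.05);")
  cfg <- simulation_config(
    tree = strong,
    marker_plan = tibble::tibble(name = "m1", class = "cpCDS",
                                 length = 4000L, rate = 1),
    seed = 17)
  ds <- simulate_alignment(cfg)
  tr <- bootstrap_support(ds$alignment, B = 200, seed = 2)
  true_keys <- tree_bipartitions(ds$true_tree)$key
  bip <- tree_bipartitions(tr)
  sup <- as.numeric(bip$key %in% true_keys) # guard: point tree may differ
  found <- bip[bip$key %in% true_keys, ]
  labs <- as.numeric(tr$node.label[found$node - length(tr$tip.label)])
  expect_gte(min(labs), 95)
  expect_equal(rf_distance(tr, ds$true_tree), 0L)
})

test_that("mean_support averages internal labels and survives newick round-trips", {
  tr <- read_newick("((A,B)88,(C,D)72);")
  expect_equal(mean_support(tr), 80)
  expect_equal(mean_support(read_newick(write_newick(tr))), 80)
  unlabeled <- read_newick("((A,B),(C,D));")
  expect_true(is.na(mean_support(unlabeled)))
})

test_that("pruning restricts the comparison tree to shared leaves", {
  big <- simulate_tree(10, seed = 4)
  keep <- big$tip.label[1:6]
  pr <- prune_to_leaves(big, keep)
  expect_setequal(pr$tip.label, keep)
  expect_error(prune_to_leaves(big, big$tip.label[1:2]), "fewer than 3")
})
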