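# Site classes, K80 distances, nucleotide diversity, sliding windows.

test_that("site classes follow the per-column state definitions", {
  aln <- dna_alignment(rbind(
    s1 = c("A", "A", "A", "A"),
    s2 = c("A", "A", "-", "C"),
    s3 = c("C", "A", "C", "G"),
    s4 = c("C", "C", "-", "T")
  ))
  # col1 AACC: variable + PIS; col2 AAAC: variable, not PIS;
  # col3 A-C-: variable, not PIS; col4 all different: variable, not PIS
  sc <- site_classes(aln)
  expect_equal(sc$variable_sites, 4L)
  expect_equal(sc$parsimony_informative_sites, 1L)
  expect_equal(sc$gap_sites, 1L)
  expect_equal(sc$mean_ungapped_length, mean(c(4, 3, 4, 3)))

  const <- dna_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  sc0 <- site_classes(const)
  expect_equal(sc0$variable_sites, 0L)
  expect_equal(sc0$parsimony_informative_sites, 0L)
  expect_error(site_classes(dna_alignment(matrix("A", 2, 0,
    dimnames = list(c("a", "b"), NULL)))), "zero-width")
})

test_that("site classes match the exhaustive census oracle on random alignments", {
  for (seed in 1:60) {
    aln <- random_alignment(sample(2:8, 1), sample(10:60, 1),
                            p_gap = runif(1, 0, 0.4), seed = seed)
    sc <- site_classes(aln)
    orc <- oracle_site_census(aln)
    expect_identical(sc$variable_sites, orc$variable)
    expect_identical(sc$parsimony_informative_sites, orc$pis)
    expect_true(sc$parsimony_informative_sites <= sc$variable_sites)
    expect_true(sc$variable_sites <= sc$aligned_length)
  }
})

test_that("K80 distance matches its closed form and flags saturation", {
  expect_equal(k80_distance("ACGTACGT", "ACGTACGT"), 0)
  # L = 100, 10 transitions (A->G), 5 transversions (A->C)
  x <- paste(rep("A", 100), collapse = "")
  y <- paste(c(rep("G", 10), rep("C", 5), rep("A", 85)), collapse = "")
  expect_equal(k80_distance(x, y), 0.1701812, tolerance = 1e-5 / 0.17)
  # saturation boundary: P = 0.5, Q = 0
  z <- paste(c(rep("G", 50), rep("A", 50)), collapse = "")
  expect_error(k80_distance(x, z), class = "plastomarker_saturation")
  expect_error(k80_distance("----", "ACGT"), "no comparable")
  # pairwise deletion: gapped/ambiguous sites drop out
  expect_equal(k80_distance("ACGTN-", "ACGAAA"),
               k80_distance("ACGT", "ACGA"))
})

test_that("K80 reduces to the transversion-only form and the P+Q limit", {
  # transversions only: d = -1/4 ln(1-2Q) - 1/2 ln(1-Q)
  for (nq in c(2, 5, 10)) {
    L <- 100
    x <- paste(rep("A", L), collapse = "")
    y <- paste(c(rep("C", nq), rep("A", L - nq)), collapse = "")
    Q <- nq / L
    expect_equal(k80_distance(x, y), -0.25 * log(1 - 2 * Q) - 0.5 * log(1 - Q))
  }
  # small divergence: d -> P + Q (within 5% at P+Q <= 0.01)
  L <- 1000
  x <- paste(rep("A", L), collapse = "")
  y <- paste(c(rep("G", 6), rep("C", 4), rep("A", L - 10)), collapse = "")
  expect_equal(k80_distance(x, y), 0.01, tolerance = 0.05)
})

test_that("mean K80 averages defined pairs and agrees with ape", {
  const <- dna_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC"))
  expect_equal(mean_k80(const), 0)

  # related sequences (simulated under K2P) so no pair saturates
  aln <- simulate_alignment(simulation_config(
    n_taxa = 5,
    marker_plan = tibble::tibble(name = "m", class = "cpCDS",
                                 length = 600L, rate = 0.5),
    seed = 42))$alignment
  D <- distance_matrix(aln)
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(unclass(aln)), model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(D[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
  expect_equal(mean_k80(aln), mean(ref[upper.tri(ref)]), tolerance = 1e-10)

  # hand-computed three-pair mean
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("G", 10), rep("A", 90)), collapse = "")
  c3 <- paste(c(rep("A", 90), rep("C", 10)), collapse = "")
  d_ab <- -0.5 * log(1 - 2 * 0.1) - 0.25 * log(1)
  d_ac <- -0.5 * log(1 - 0.1) - 0.25 * log(1 - 0.2)
  # b vs c3: 10 transitions + 10 transversions
  d_bc <- -0.5 * log(1 - 2 * 0.1 - 0.1) - 0.25 * log(1 - 0.2)
  expect_equal(mean_k80(dna_alignment(c(a = a, b = b, c = c3))),
               mean(c(d_ab, d_ac, d_bc)))
})

test_that("nucleotide diversity matches examples, the brute-force oracle and shuffling", {
  two <- dna_alignment(c(a = "AAAAAAAAAA", b = "CAAAAAAAAA"))
  expect_equal(nucleotide_diversity(two), 0.1)

  three <- dna_alignment(c(a = "AAAA", b = "AACC", c = "ACCC"))
  # pairs: a-b 2/4, a-c 3/4, b-c 1/4
  expect_equal(nucleotide_diversity(three), mean(c(2, 3, 1) / 4))

  for (seed in 1:12) {
    aln <- random_alignment(sample(3:10, 1), sample(50:200, 1),
                            p_gap = runif(1, 0, 0.3), seed = 100 + seed)
    expect_equal(nucleotide_diversity(aln), oracle_pi(aln))
    shuffled <- unclass(aln)[, withr::with_seed(seed, sample(ncol(aln)))]
    expect_equal(nucleotide_diversity(dna_alignment(shuffled)),
                 nucleotide_diversity(aln))
    # under complete data pi cannot exceed the variable-site fraction
    if (!any(unclass(aln) == "-")) {
      sc <- site_classes(aln)
      expect_lte(nucleotide_diversity(aln),
                 sc$variable_sites / sc$aligned_length + 1e-12)
    }
  }
})

test_that("sliding windows tile the alignment and localize divergence", {
  const <- random_alignment(4, 2000, seed = 9)
  m <- unclass(const)
  for (i in 2:4) m[i, ] <- m[1, ]
  aln0 <- dna_alignment(m)
  tr0 <- sliding_window_pi(aln0, window = 800, step = 200)
  expect_equal(nrow(tr0), 7L)   # floor((2000-800)/200)+1
  expect_true(all(tr0$pi == 0))
  expect_equal(tr0$start, seq(0L, 1200L, by = 200L))

  # one divergent 100-column block raises exactly the overlapping windows
  m2 <- m
  m2[2, 1001:1100] <- chartr("ACGT", "GTAC", m2[2, 1001:1100])
  tr1 <- sliding_window_pi(dna_alignment(m2), window = 800, step = 200)
  overlaps <- tr1$start < 1100 & (tr1$start + 800) > 1000
  expect_true(all(tr1$pi[overlaps] > 0))
  expect_true(all(tr1$pi[!overlaps] == 0))

  expect_warning(short <- sliding_window_pi(aln0[, 1:100] |> (\(x) {
    class(x) <- c("dna_alignment", "matrix", "array"); x })(),
    window = 800, step = 200), "narrower")
  expect_equal(nrow(short), 1L)
})
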