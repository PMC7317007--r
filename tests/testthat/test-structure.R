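# Quadripartite architecture, composition and pseudogene screening.

test_that("a planted inverted repeat is recovered with exact region lengths", {
  g <- plant_quadripartite(ir_length = 1000, ssc_length = 2000,
                           total_length = 12000, seed = 5)
  part <- find_inverted_repeat(g, min_len = 500)
  expect_equal(attr(part, "ir_length"), 1000L)
  lens <- setNames(part$length, part$region)
  expect_equal(lens[["LSC"]], 8000L)
  expect_equal(lens[["SSC"]], 2000L)
  expect_equal(lens[["IRa"]], 1000L)
  expect_equal(lens[["IRb"]], 1000L)
  # partition invariants: disjoint cover and the IR mirror identity
  expect_equal(sum(part$length), 12000L)
  expect_equal(region_sequence(part, g, "IRa"),
               revcomp(region_sequence(part, g, "IRb")))
})

test_that("IR detection matches the all-pairs oracle on small planted genomes", {
  cases <- list(
    list(ir = 150, ssc = 300, total = 2000, seed = 21),
    list(ir = 220, ssc = 500, total = 2600, seed = 22),
    list(ir = 400, ssc = 150, total = 3000, seed = 23)
  )
  for (cs in cases) {
    g <- plant_quadripartite(cs$ir, cs$ssc, cs$total, seed = cs$seed)
    part <- find_inverted_repeat(g, min_len = 100)
    expect_equal(attr(part, "ir_length"), oracle_ir_length(g, 100L),
                 info = sprintf("total=%d ir=%d", cs$total, cs$ir))
  }
})

test_that("IR detection is rotation invariant and degenerates gracefully", {
  g <- plant_quadripartite(800, 1500, 10000, seed = 6)
  part <- find_inverted_repeat(g, min_len = 500)
  rot <- function(s, o) paste0(substr(s, o + 1, nchar(s)), substr(s, 1, o))
  for (off in c(1234, 5000, 9999)) {
    p2 <- find_inverted_repeat(rot(g, off), min_len = 500)
    expect_equal(sort(p2$length), sort(part$length))
    expect_equal(p2$start[p2$region == "LSC"],
                 (part$start[part$region == "LSC"] - off) %% 10000L)
  }

  expect_warning(p3 <- find_inverted_repeat(random_dna(5000, seed = 7),
                                            min_len = 500),
                 "degenerate")
  expect_true(attr(p3, "degenerate"))
  expect_equal(p3$length[p3$region == "LSC"], 5000L)
  expect_equal(attr(p3, "ir_length"), 0L)

  expect_error(find_inverted_repeat(random_dna(5000, seed = 7), min_len = 500,
                                    circular = FALSE),
               "circular")
  expect_error(find_inverted_repeat(random_dna(5000, seed = 7), min_len = 50),
               "at least 100")
})

test_that("gc_content follows the S/W-aware definition and is strand symmetric", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATATAT"), 0.0)
  expect_equal(gc_content("ACGT"), 0.5)
  # S counts as G+C, W as A+T, other ambiguity codes are ignored entirely
  expect_equal(gc_content("ASWN"), 1 / 3)
  expect_error(gc_content(""), "empty")
  for (seed in 1:5) {
    s <- random_dna(200, seed = seed)
    expect_equal(gc_content(s), gc_content(revcomp(s)))
  }
})

test_that("gene inventory assigns features to regions by majority rule", {
  g <- plant_quadripartite(1000, 2000, 12000, seed = 5)
  part <- find_inverted_repeat(g, min_len = 500)
  # LSC = [0,8000), IRb = [8000,9000), SSC = [9000,11000), IRa = [11000,12000)
  feats <- tibble::tibble(
    gene = c("cdsA", "cdsB", "trnQ", "rrnX", "rrnX", "straddle"),
    class = c("CDS", "CDS", "tRNA", "rRNA", "rRNA", "CDS"),
    strand = "+",
    parts = list(matrix(c(10L, 400L), ncol = 2),
                 matrix(c(500L, 900L), ncol = 2),
                 matrix(c(9100L, 9200L), ncol = 2),
                 matrix(c(8100L, 8500L), ncol = 2),
                 matrix(c(11100L, 11500L), ncol = 2),
                 matrix(c(7900L, 8040L), ncol = 2)),  # 100 bp LSC, 40 bp IRb
    pseudo = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  p <- plastome(g, feats, circular = TRUE)
  inv <- gene_inventory(p, part)
  get <- function(reg, cls) {
    v <- inv$n[inv$region == reg & inv$class == cls]
    if (length(v) == 0) 0L else v
  }
  expect_equal(get("LSC", "CDS"), 3L)  # cdsA, cdsB, straddle (majority LSC)
  expect_equal(get("SSC", "tRNA"), 1L)
  expect_equal(get("IRa", "rRNA"), 1L)
  expect_equal(get("IRb", "rRNA"), 1L)
  expect_equal(sum(inv$n), 6L)
  expect_equal(sum(inv$n_pseudo), 1L)

  comp <- composition_table(p, part)
  expect_equal(comp$genes[comp$region == "Genome"], 6L)
  expect_equal(comp$pseudogenes[comp$region == "Genome"], 1L)
  expect_equal(comp$size_bp[comp$region == "Genome"], 12000L)

  empty <- plastome(g, circular = TRUE)
  expect_equal(nrow(gene_inventory(empty, part)), 0L)
})

test_that("pseudogene screening reports each structural defect", {
  expect_length(screen_pseudogene("ATGAAATAA"), 0L)
  expect_equal(screen_pseudogene("ATGTAAAAATAA"), "internal_stop")
  expect_setequal(screen_pseudogene("ATGAAAA"),
                  c("length_not_multiple_of_3", "missing_stop"))
  expect_true("missing_start" %in% screen_pseudogene("CCCAAATAA"))
  # GTG is a legal plastid start
  expect_length(screen_pseudogene("GTGAAATAA"), 0L)
  expect_error(screen_pseudogene("ATG-AATAA"), "gap")

  # 300-codon intact ORF with a TGA substituted at codon 150
  non_stop <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                        c("A","C","G","T")), 1, paste, collapse = ""),
                      c("TAA", "TAG", "TGA"))
  codons <- withr::with_seed(31, sample(non_stop, 300, replace = TRUE))
  codons[1] <- "ATG"; codons[300] <- "TAA"
  expect_length(screen_pseudogene(paste(codons, collapse = "")), 0L)
  codons[150] <- "TGA"
  expect_equal(screen_pseudogene(paste(codons, collapse = "")), "internal_stop")
  # truncation to exactly half the expected length is not "small"; under
  # half (expected 1000 bp vs 450 bp observed ORF) is
  expect_equal(screen_pseudogene(paste(codons, collapse = ""),
                                 expected_length = 900),
               "internal_stop")
  expect_setequal(screen_pseudogene(paste(codons, collapse = ""),
                                    expected_length = 1000),
                  c("internal_stop", "small_orf"))
})

test_that("screen_cds splices multi-part minus-strand features before screening", {
  # minus-strand CDS "ATGAAATAA" split over two exons
  cds <- "ATGAAATAA"
  genome_plus <- revcomp(cds)  # 9 bp
  seq <- paste0("CCCCC", substr(genome_plus, 1, 4), "GGGGG",
                substr(genome_plus, 5, 9), "CCCCC")
  feats <- tibble::tibble(
    gene = "negGene", class = "CDS", strand = "-",
    parts = list(matrix(c(5L, 9L, 14L, 19L), ncol = 2, byrow = TRUE)),
    pseudo = FALSE
  )
  p <- plastome(seq, feats, circular = FALSE)
  res <- screen_cds(p)
  expect_false(res$flagged)
})
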