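# Independent brute-force oracles and tiny fixture builders shared by the
# suite. The oracles are deliberately naive (per-column loops, all-pairs
# scans) so they stay independent of the vectorized implementations.

random_alignment <- function(n_taxa, width, p_gap = 0, seed = 1) {
  withr::with_seed(seed, {
    alphabet <- c("A", "C", "G", "T")
    m <- matrix(sample(alphabet, n_taxa * width, replace = TRUE),
                nrow = n_taxa,
                dimnames = list(paste0("s", seq_len(n_taxa)), NULL))
    if (p_gap > 0) m[runif(length(m)) < p_gap] <- "-"
    dna_alignment(m)
  })
}

random_dna <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# per-column state census: variable / parsimony-informative counts
oracle_site_census <- function(aln) {
  m <- unclass(aln)
  variable <- 0L
  pis <- 0L
  for (j in seq_len(ncol(m))) {
    states <- m[, j]
    states <- states[states %in% c("A", "C", "G", "T")]
    tab <- table(states)
    if (length(tab) >= 2) variable <- variable + 1L
    if (sum(tab >= 2) >= 2) pis <- pis + 1L
  }
  list(variable = variable, pis = pis)
}

# nucleotide diversity by an explicit double loop over pairs and sites
oracle_pi <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diff <- 0L; comp <- 0L
      for (s in seq_len(ncol(m))) {
        a <- m[i, s]; b <- m[j, s]
        if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
          comp <- comp + 1L
          if (a != b) diff <- diff + 1L
        }
      }
      if (comp > 0) vals <- c(vals, diff / comp)
    }
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# maximal reverse-complement repeat length on a circle by an all-pairs
# anti-diagonal scan (vectorized per diagonal, still O(n^2))
oracle_ir_length <- function(seq, min_len) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  best <- 0L
  for (d in 0:(n - 1)) {
    i <- 0:(n - 1)
    j <- (d - i) %% n
    match_vec <- s[i + 1] == comp[s[j + 1]]
    # circular runs of TRUE
    mv <- c(match_vec, match_vec)
    r <- rle(mv)
    ends <- cumsum(r$lengths)
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      L <- min(r$lengths[k], n)
      if (L < min_len) next
      a <- (ends[k] - r$lengths[k]) %% n
      b <- (d - (a + L - 1)) %% n
      # shrink until the two copies are disjoint on the circle
      while (L >= min_len) {
        da <- (b - a) %% n; db <- (a - b) %% n
        if (2 * L <= n && da >= L && db >= L) break
        L <- L - 1L
        b <- (b + 1L) %% n
      }
      if (L >= min_len) best <- max(best, L)
    }
  }
  best
}

# hand-rolled GenBank record text for parser tests
genbank_fixture <- function(seq, feature_lines, circular = TRUE, id = "toy") {
  n <- nchar(seq)
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     %s UNA 01-JAN-2000",
            id, n, if (circular) "circular" else "linear"),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    feature_lines,
    "ORIGIN"
  )
  for (s in seq(1L, n, by = 60L)) {
    lines <- c(lines, sprintf("%9d %s", s, tolower(substr(seq, s, min(n, s + 59L)))))
  }
  c(lines, "//")
}

expect_same_split_set <- function(t1, t2) {
  expect_setequal(tree_bipartitions(t1)$key, tree_bipartitions(t2)$key)
}

# the printed per-marker summary of the published top-10 table, used as
# *input* data for ranking tests
published_top10 <- function() {
  tibble::tibble(
    marker = c("accD", "ycf1", "ndhD", "trnK", "psbE-rpl20",
               "petD", "ccsA", "clpP", "rpoC2", "rpoC1"),
    bp_mean = c(1876, 1565, 1421, 2570, 1731, 1265, 1008, 359, 4101, 2468),
    variable_sites = c(966, 958, 210, 173, 242, 69, 110, 112, 165, 86),
    pis = c(586, 429, 52, 45, 68, 27, 49, 64, 47, 35),
    tree_distance = c(10, 8, 6, 8, 8, 8, 8, 8, 8, 8),
    mean_bootstrap = c(88, 76, 79, 82, 77, 75, 73, 70, 69, 69)
  )
}

published_bounds <- function() {
  list(variable = c(0, 966), bootstrap = c(0, 89), distance = c(6, 28))
}
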