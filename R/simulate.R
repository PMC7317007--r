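# Synthetic data: plastome-like alignments evolved along a known tree
# under the Kimura two-parameter process, with per-marker rate
# heterogeneity, optional phylogenetically coherent indels, an annotated
# reference whose features define the marker classes, and ground-truth
# labels. Every stage of the pipeline is testable against these without
# any download.
#
# The default configuration emulates the shape of a genus-level plastome
# survey: 17 taxa, ~20 markers of the three classes with one strongly
# accelerated ("hot") marker, transition/transversion ratio kappa = 2,
# equal base composition, branch lengths ~ Exp(mean 0.05 subst/site).

#' Simulate a random unrooted binary tree
#'
#' Topology by sequential random attachment (each new leaf attaches to
#' an edge drawn uniformly from the current tree), branch lengths drawn
#' i.i.d. exponential with mean 0.05 substitutions/site. Deterministic
#' given `seed`.
#'
#' @param n_taxa Number of leaves (>= 4).
#' @param seed Integer seed.
#' @param mean_branch Mean branch length (default 0.05).
#' @return An unrooted ape `phylo` with tips `t1 ... tn`.
#' @export
simulate_tree <- function(n_taxa, seed = 1L, mean_branch = 0.05) {
  if (n_taxa < 4L) stop("simulate_tree(): need at least 4 taxa")
  with_seed(seed, {
    # provisional ids: tips 1..n, internals n+1, n+2, ...
    nid <- n_taxa + 1L
    edges <- list(c(nid, 1L), c(nid, 2L), c(nid, 3L))
    for (k in 4:n_taxa) {
      e <- sample.int(length(edges), 1L)
      ab <- edges[[e]]
      nid <- nid + 1L
      edges[[e]] <- c(ab[1], nid)
      edges[[length(edges) + 1L]] <- c(nid, ab[2])
      edges[[length(edges) + 1L]] <- c(nid, k)
    }
    em <- do.call(rbind, edges)
    # renumber internals n+1 .. 2n-2 in DFS order from the first internal
    nnode <- n_taxa - 2L
    newid <- integer(max(em))
    newid[seq_len(n_taxa)] <- seq_len(n_taxa)
    counter <- n_taxa
    visited <- logical(max(em))
    stack <- n_taxa + 1L
    order_edges <- integer(0)
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      visited[v] <- TRUE
      if (v > n_taxa) { counter <- counter + 1L; newid[v] <- counter }
      inc <- which(em[, 1] == v | em[, 2] == v)
      for (i in inc) {
        w <- if (em[i, 1] == v) em[i, 2] else em[i, 1]
        if (!visited[w]) {
          order_edges <- c(order_edges, i)
          em[i, ] <- c(v, w)  # orient parent -> child
          stack <- c(stack, w)
        }
      }
    }
    em <- em[order_edges, , drop = FALSE]
    em2 <- cbind(newid[em[, 1]], newid[em[, 2]])
    tr <- list(
      edge = em2,
      tip.label = paste0("t", seq_len(n_taxa)),
      Nnode = nnode,
      edge.length = stats::rexp(nrow(em2), rate = 1 / mean_branch)
    )
    class(tr) <- "phylo"
    attr(tr, "order") <- NULL
    ape::reorder.phylo(tr, "cladewise")
  })
}

#' Default marker plan with one hot marker
#'
#' Twenty markers: one strongly accelerated 1,800 bp coding marker
#' (rate multiplier 4) and nineteen background markers of 300-1,500 bp
#' with multipliers 0.2-1, cycling through the three marker classes.
#' The hot marker is the ground-truth best marker.
#'
#' @param n_markers Total number of markers (default 20).
#' @param seed Integer seed for the background lengths/rates.
#' @return Tibble `name`, `class`, `length`, `rate`.
#' @export
hot_marker_plan <- function(n_markers = 20L, seed = 1L) {
  stopifnot(n_markers >= 2L)
  with_seed(seed, {
    classes <- rep(c("cpCDS", "cpNCDS", "cpIGS"), length.out = n_markers - 1L)
    lens <- sample(300:1500, n_markers - 1L, replace = TRUE)
    rates <- stats::runif(n_markers - 1L, 0.2, 1)
    tibble::tibble(
      name = c("hot1", sprintf("bg%02d", seq_len(n_markers - 1L))),
      class = c("cpCDS", classes),
      length = as.integer(c(1800L, lens)),
      rate = c(4, rates)
    )
  })
}

#' Simulation configuration
#'
#' @param n_taxa Number of taxa (default 17).
#' @param tree Optional newick string or `phylo`; simulated when `NULL`.
#' @param kappa Transition/transversion *rate* ratio (default 2).
#' @param base_composition Length-4 probability vector (A, C, G, T).
#' @param marker_plan Tibble `name`, `class`, `length`, `rate`; default
#'   [hot_marker_plan()] drawn from `seed`.
#' @param ir_plan Optional list `(ir_length, ssc_length, total_length)`
#'   for [plant_quadripartite()].
#' @param indel_rate Indel events per site per unit branch length
#'   (default 0).
#' @param seed Integer master seed; all draws flow from named substreams.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_taxa = 17L, tree = NULL, kappa = 2,
                              base_composition = rep(0.25, 4),
                              marker_plan = NULL, ir_plan = NULL,
                              indel_rate = 0, seed = 1L) {
  stopifnot(kappa > 0, length(base_composition) == 4,
            abs(sum(base_composition) - 1) < 1e-8, indel_rate >= 0)
  if (is.null(marker_plan)) marker_plan <- hot_marker_plan(seed = seed)
  if (nrow(marker_plan) == 0L) stop("marker plan must not be empty")
  stopifnot(all(marker_plan$length > 0), all(is.finite(marker_plan$rate)),
            all(marker_plan$rate >= 0))
  structure(
    list(n_taxa = n_taxa, tree = tree, kappa = kappa,
         base_composition = base_composition, marker_plan = marker_plan,
         ir_plan = ir_plan, indel_rate = indel_rate, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# K2P change probabilities for branch length t (expected substitutions
# per site) and rate ratio kappa, with the generator normalized to one
# expected substitution per site per unit time.
k2p_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv = 0.5 - 0.5 * e1)  # split evenly over the two transversion targets
}

TS_PARTNER <- c(3L, 4L, 1L, 2L)
TV_PARTNER1 <- c(2L, 1L, 2L, 1L)
TV_PARTNER2 <- c(4L, 3L, 4L, 3L)

# evolve an integer-coded parent vector (1..4; 0 = gap) along one branch;
# t_by_site has one distinct value per marker, so probabilities are
# computed once per unique branch-length scaling
evolve_branch <- function(parent, t_by_site, kappa) {
  child <- parent
  live <- which(parent > 0L)
  if (length(live) == 0L) return(child)
  u <- stats::runif(length(live))
  tt <- t_by_site[live]
  ut <- unique(tt)
  pr <- vapply(ut, k2p_probs, numeric(3), kappa = kappa)
  idx <- match(tt, ut)
  p_same <- pr[1, idx]
  p_ts <- pr[2, idx]
  base <- parent[live]
  pick_ts <- u >= p_same & u < p_same + p_ts
  pick_tv1 <- u >= p_same + p_ts & u < p_same + p_ts + (1 - p_same - p_ts) / 2
  pick_tv2 <- u >= p_same + p_ts + (1 - p_same - p_ts) / 2
  out <- base
  out[pick_ts] <- TS_PARTNER[base[pick_ts]]
  out[pick_tv1] <- TV_PARTNER1[base[pick_tv1]]
  out[pick_tv2] <- TV_PARTNER2[base[pick_tv2]]
  child[live] <- out
  child
}

#' Simulate a marker-structured alignment along a tree
#'
#' Draws a root sequence marker by marker from the base composition and
#' evolves it along the (given or simulated) tree under the K2P process,
#' with each marker's rate multiplier scaling all branch lengths.
#' Optional indels are applied per branch after substitution (Poisson
#' count, geometric lengths with mean 3, insertion/deletion
#' equiprobable) and are inherited by descendants, so gap patterns are
#' phylogenetically coherent. The first taxon (`t1`) is the annotated
#' reference: CDS features for cpCDS markers, tRNA features for cpNCDS
#' markers, and unannotated gaps for cpIGS markers, abutting in plan
#' order.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_dataset` list: `reference` ([plastome()],
#'   linear), `alignment` ([dna_alignment()]), `true_tree` (`phylo`),
#'   `truth` (marker plan tibble), `partition` (planted
#'   quadripartite genome, when `ir_plan` is set), `config`.
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed
  plan <- config$marker_plan
  tr <- config$tree
  if (is.null(tr)) {
    tr <- simulate_tree(config$n_taxa, seed = substream_seed(seed, 1L))
  } else if (is.character(tr)) {
    tr <- read_newick(tr)
  }
  n_tip <- length(tr$tip.label)
  L <- sum(plan$length)
  site_marker <- rep(seq_len(nrow(plan)), plan$length)
  site_rate <- plan$rate[site_marker]

  root_vec <- with_seed(substream_seed(seed, 2L), {
    sample.int(4L, L, replace = TRUE, prob = config$base_composition)
  })

  # root the traversal at the first internal node; preorder over edges
  tr2 <- ape::reorder.phylo(tr, "cladewise")
  seqs <- vector("list", n_tip + tr2$Nnode)
  root <- n_tip + 1L
  seqs[[root]] <- root_vec
  width <- L
  for (e in seq_len(nrow(tr2$edge))) {
    par <- tr2$edge[e, 1]
    chd <- tr2$edge[e, 2]
    t_e <- tr2$edge.length[e]
    child <- with_seed(substream_seed(seed, 100L + e), {
      evolve_branch(seqs[[par]], site_rate * t_e, config$kappa)
    })
    if (config$indel_rate > 0) {
      res <- with_seed(substream_seed(seed, 100000L + e), {
        apply_indels(child, config$indel_rate * t_e, config$base_composition)
      })
      child <- res$child
      if (length(res$insert_at) > 0) {
        # splice gap columns into every stored sequence; `child` already
        # carries the inserted residues. Inserted columns inherit the
        # marker (and rate) of their flanking site.
        for (v in seq_along(seqs)) {
          if (!is.null(seqs[[v]]) && v != chd) {
            seqs[[v]] <- splice_gaps(seqs[[v]], res$insert_at)
          }
        }
        site_marker <- splice_values(site_marker, res$insert_at, res$insert_rate_from)
        site_rate <- plan$rate[site_marker]
        width <- width + length(res$insert_at)
      }
    }
    seqs[[chd]] <- child
  }

  m <- matrix("-", nrow = n_tip, ncol = width,
              dimnames = list(tr2$tip.label, NULL))
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n_tip)) {
    v <- seqs[[i]]
    m[i, v > 0L] <- bases[v[v > 0L]]
  }
  aln <- structure(m, class = c("dna_alignment", "matrix", "array"))

  # reference annotation on the ungapped first-taxon sequence
  ref_label <- tr2$tip.label[1]
  ref_row <- seqs[[1L]]
  marker_width <- tabulate(site_marker, nbins = nrow(plan))
  marker_col_end <- cumsum(marker_width)
  marker_col_start <- c(0L, marker_col_end[-length(marker_col_end)])
  nongap_before <- cumsum(ref_row > 0L)
  ref_pos <- function(col) if (col == 0L) 0L else nongap_before[col]
  feats <- list()
  for (j in seq_len(nrow(plan))) {
    s <- ref_pos(marker_col_start[j])
    e <- ref_pos(marker_col_end[j])
    if (e <= s) next
    cls <- switch(plan$class[j], cpCDS = "CDS", cpNCDS = "tRNA", cpIGS = NA_character_)
    if (is.na(cls)) next
    feats[[length(feats) + 1L]] <- tibble::tibble(
      gene = plan$name[j], class = cls, strand = "+",
      parts = list(feature_part(s, e)), pseudo = FALSE
    )
  }
  ref_seq <- paste(bases[ref_row[ref_row > 0L]], collapse = "")
  reference <- plastome(ref_seq,
                        if (length(feats)) dplyr::bind_rows(feats) else empty_features(),
                        circular = FALSE, id = ref_label)

  planted <- NULL
  if (!is.null(config$ir_plan)) {
    planted <- plant_quadripartite(
      ir_length = config$ir_plan$ir_length,
      ssc_length = config$ir_plan$ssc_length,
      total_length = config$ir_plan$total_length,
      seed = substream_seed(seed, 3L)
    )
  }

  structure(
    list(reference = reference, alignment = aln, true_tree = tr2,
         truth = plan, planted = planted, config = config),
    class = "synthetic_dataset"
  )
}

# indels on one child vector: returns modified child plus positions of
# inserted columns (to be spliced as gaps into all other rows)
apply_indels <- function(child, rate_t, base_composition) {
  live <- sum(child > 0L)
  n_ev <- stats::rpois(1L, rate_t * live)
  insert_at <- integer(0)
  insert_rate_from <- integer(0)
  for (ev in seq_len(n_ev)) {
    len <- stats::rgeom(1L, 1 / 3) + 1L
    if (stats::runif(1) < 0.5) {
      # deletion of `len` consecutive live positions
      idx_live <- which(child > 0L)
      if (length(idx_live) <= len + 4L) next
      s <- sample.int(length(idx_live) - len, 1L)
      child[idx_live[s:(s + len - 1L)]] <- 0L
    } else {
      pos <- sample.int(length(child) + 1L, 1L) - 1L  # insert after column pos
      newbases <- sample.int(4L, len, replace = TRUE, prob = base_composition)
      child <- append(child, newbases, after = pos)
      # earlier insertions downstream of this one shift right
      insert_at[insert_at > pos] <- insert_at[insert_at > pos] + len
      insert_at <- c(insert_at, pos + seq_len(len))
      # source column (for marker/rate inheritance) in pre-branch coords
      src <- max(1L, pos - sum(insert_at <= pos))
      insert_rate_from <- c(insert_rate_from, rep(src, len))
    }
  }
  list(child = child, insert_at = insert_at, insert_rate_from = insert_rate_from)
}

splice_gaps <- function(v, insert_at) {
  out <- integer(length(v) + length(insert_at))
  out[insert_at] <- 0L
  out[-insert_at] <- v
  out
}

splice_values <- function(v, insert_at, from) {
  out <- vector(mode = mode(v), length(v) + length(insert_at))
  out[-insert_at] <- v
  out[insert_at] <- v[pmin(from, length(v))]
  out
}

#' Plant a quadripartite circular genome
#'
#' Random circle `LSC + IRa + SSC + IRb` with `IRb` the exact reverse
#' complement of `IRa` — the fixture closing the loop with
#' [find_inverted_repeat()].
#'
#' @param ir_length,ssc_length,total_length Region sizes in bp
#'   (LSC takes the remainder).
#' @param seed Integer seed.
#' @return A single DNA string (circular by construction).
#' @export
plant_quadripartite <- function(ir_length = 1000L, ssc_length = 2000L,
                                total_length = 12000L, seed = 1L) {
  lsc <- total_length - 2L * ir_length - ssc_length
  if (lsc <= 0L) stop("region lengths exceed the total genome length")
  if (lsc < 2L || ssc_length < 2L) stop("single-copy regions must be >= 2 bp")
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    lscv <- sample(bases, lsc, replace = TRUE)
    sscv <- sample(bases, ssc_length, replace = TRUE)
    ira <- paste(sample(bases, ir_length, replace = TRUE), collapse = "")
    # guard the four boundaries so the planted repeat is exactly maximal:
    # extending IRa left pairs lsc[last] with comp(lsc[first]) across the
    # origin; extending IRa right pairs ssc[first] with comp(ssc[last])
    if (lscv[lsc] == COMPLEMENT[lscv[1]]) {
      lscv[lsc] <- sample(setdiff(bases, COMPLEMENT[lscv[1]]), 1)
    }
    if (sscv[1] == COMPLEMENT[sscv[ssc_length]]) {
      sscv[1] <- sample(setdiff(bases, COMPLEMENT[sscv[ssc_length]]), 1)
    }
    paste0(paste(lscv, collapse = ""), ira,
           paste(sscv, collapse = ""), revcomp(ira))
  })
}
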