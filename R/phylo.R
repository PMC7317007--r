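# Distance-based tree inference (neighbor joining over K80 distances)
# with nonparametric bootstrap, bipartition machinery, Robinson-Foulds
# distances and support aggregation. Externally computed newick trees
# are accepted anywhere a tree is consumed (everything operates on ape
# `phylo` objects).

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (ape's implementation). Negative branch
#' lengths, an occasional NJ artifact, are clamped to zero with the
#' deficit transferred to the sibling edge so path lengths are roughly
#' preserved.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) with taxa dimnames.
#' @return An unrooted ape `phylo`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("nj_tree(): need at least 3 taxa")
  if (any(!is.finite(d))) stop("nj_tree(): non-finite distance matrix entries")
  tr <- ape::nj(d)
  neg <- which(tr$edge.length < 0)
  for (i in neg) {
    parent <- tr$edge[i, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), i)
    if (length(sibs) > 0) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[i]
    }
    tr$edge.length[i] <- 0
  }
  tr
}

#' Internal bipartitions of a tree
#'
#' Each internal edge splits the leaves in two; the split is canonicalized
#' as the sorted leaf set on the side *not* containing the alphabetically
#' first leaf, serialized to a string key. Trivial splits (a single leaf)
#' are excluded, so polytomies need no special casing.
#'
#' @param tree An ape `phylo`.
#' @return Tibble `node` (internal node id), `key` (canonical split).
#' @export
tree_bipartitions <- function(tree) {
  keys <- bipartition_keys(tree)
  out <- tibble::tibble(node = as.integer(names(keys)), key = unname(keys))
  dplyr::distinct(out, .data$key, .keep_all = TRUE)
}

# lean core shared with the bootstrap loop: named character vector of
# canonical split keys, names = internal node ids
bipartition_keys <- function(tree) {
  n <- length(tree$tip.label)
  labs_sorted <- sort(tree$tip.label)
  anchor <- labs_sorted[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- character(0)
  nodes <- integer(0)
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (anchor %in% side) side <- setdiff(labs, side)
    k <- length(side)
    if (k < 2L || k > n - 2L) next
    nodes <- c(nodes, n + i)
    keys <- c(keys, paste(sort(side), collapse = ";"))
  }
  stats::setNames(keys, nodes)
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference of the two trees' internal
#' bipartition sets. Leaf sets must match.
#'
#' @param t1,t2 ape `phylo` objects on the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("rf_distance(): trees have different leaf sets")
  }
  k1 <- tree_bipartitions(t1)$key
  k2 <- tree_bipartitions(t2)$key
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' NJ tree with nonparametric bootstrap support
#'
#' Builds the point-estimate NJ tree from the K80 distance matrix of the
#' full alignment, then resamples alignment columns with replacement
#' (original width) B times; the support of each internal edge is the
#' percentage of replicate trees containing the same bipartition.
#' Deterministic given `seed`: replicate r draws from a substream
#' derived from (seed, r).
#'
#' @param aln A [dna_alignment()] (>= 3 taxa).
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return The point-estimate `phylo` with supports in `node.label`
#'   (empty labels on root/trivial nodes).
#' @export
bootstrap_support <- function(aln, B = 100L, seed = 1L) {
  stopifnot(B >= 1L)
  enc <- encode_alignment(aln)
  point <- nj_tree(dist_from_enc(enc))
  if (nrow(aln) < 4L) {
    point$node.label <- rep("", point$Nnode)
    return(point)
  }
  bip <- bipartition_keys(point)
  hits <- stats::setNames(numeric(length(bip)), unname(bip))
  n <- nrow(enc)
  L <- ncol(enc)
  # stacked base indicators (L x 4n): column resampling with replacement
  # is equivalent to reweighting columns, so every replicate's pair
  # counts come from one weighted cross-product
  tE <- t(enc)
  S <- matrix(0, nrow = L, ncol = 4L * n)
  for (b in 1:4) {
    m <- tE == b
    m[is.na(m)] <- FALSE
    S[, (b - 1L) * n + seq_len(n)] <- m
  }
  V <- S[, seq_len(n)] + S[, n + seq_len(n)] + S[, 2L * n + seq_len(n)] +
    S[, 3L * n + seq_len(n)]
  blk <- function(M, x, y) M[(x - 1L) * n + seq_len(n), (y - 1L) * n + seq_len(n)]
  used <- 0L
  sat_warned <- FALSE
  for (r in seq_len(B)) {
    w <- with_seed(substream_seed(seed, r),
                   tabulate(sample.int(L, L, replace = TRUE), nbins = L))
    M <- crossprod(S, S * w)
    compared <- crossprod(V, V * w)
    if (any(compared[upper.tri(compared)] == 0)) next
    same <- blk(M, 1, 1) + blk(M, 2, 2) + blk(M, 3, 3) + blk(M, 4, 4)
    ts <- blk(M, 1, 3) + blk(M, 3, 1) + blk(M, 2, 4) + blk(M, 4, 2)
    P <- ts / compared
    Q <- (compared - same - ts) / compared
    a <- 1 - 2 * P - Q
    bb <- 1 - 2 * Q
    D <- matrix(NA_real_, n, n, dimnames = list(rownames(enc), rownames(enc)))
    ok <- a > 0 & bb > 0
    D[ok] <- -0.5 * log(a[ok]) - 0.25 * log(bb[ok])
    diag(D) <- 0
    if (anyNA(D)) {
      sat_warned <- TRUE
      D[is.na(D)] <- 2 * max(D, na.rm = TRUE)
    }
    used <- used + 1L
    keys <- bipartition_keys(nj_tree(D))
    seen <- names(hits) %in% keys
    hits[seen] <- hits[seen] + 1
  }
  if (used == 0L) stop("bootstrap_support(): every replicate failed")
  if (used < B) warning("bootstrap_support(): ", B - used, " replicate(s) dropped")
  if (sat_warned) warning("saturated pair(s) imputed in bootstrap replicate(s)")
  support <- round(100 * hits / used, 1)
  labels <- rep("", point$Nnode)
  ntip <- length(point$tip.label)
  labels[as.integer(names(bip)) - ntip] <- as.character(support[unname(bip)])
  point$node.label <- labels
  point
}

# distance matrix straight from an encoded alignment (shared by the
# bootstrap loop, which would otherwise re-encode every replicate)
dist_from_enc <- function(enc) {
  n <- nrow(enc)
  pc <- pair_counts(enc)
  if (any(pc$compared[upper.tri(pc$compared)] == 0)) {
    stop("a pair of taxa shares no comparable sites")
  }
  P <- pc$ts / pc$compared
  Q <- pc$tv / pc$compared
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  D <- matrix(NA_real_, n, n, dimnames = list(rownames(enc), rownames(enc)))
  okd <- a > 0 & b > 0
  D[okd] <- -0.5 * log(a[okd]) - 0.25 * log(b[okd])
  diag(D) <- 0
  if (anyNA(D)) {
    mx <- max(D, na.rm = TRUE)
    warning("saturated pair(s) imputed as twice the maximum defined distance")
    D[is.na(D)] <- 2 * mx
  }
  D
}

#' Mean bootstrap support of a tree
#'
#' Arithmetic mean of the numeric internal-edge supports carried in
#' `node.label`; nodes with empty labels are skipped.
#'
#' @param tree An ape `phylo` with supports as internal node labels.
#' @return Mean support, or `NA` if no edge carries a support value.
#' @export
mean_support <- function(tree) {
  if (is.null(tree$node.label)) return(NA_real_)
  v <- suppressWarnings(as.numeric(tree$node.label))
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Prune a tree to a leaf subset
#'
#' Used to compare a marker tree (possibly missing all-gap taxa) with
#' the full-plastome tree: the comparison tree is pruned to the marker's
#' leaf set before RF computation.
#'
#' @param tree An ape `phylo`.
#' @param leaves Leaf labels to keep (>= 3).
#' @return The pruned `phylo`.
#' @export
prune_to_leaves <- function(tree, leaves) {
  keep <- intersect(tree$tip.label, leaves)
  if (length(keep) < 3L) stop("prune_to_leaves(): fewer than 3 shared leaves")
  ape::keep.tip(tree, keep)
}
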