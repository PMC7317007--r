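# Per-alignment diversity statistics: site classes, K80 distances,
# nucleotide diversity and its sliding-window profile.
#
# Gap handling is pairwise deletion throughout: a site drops out of a
# pairwise comparison when either sequence is gapped or ambiguous there,
# never for the whole alignment. Ambiguity codes are treated as missing,
# not fractionally expanded. Note this differs from DnaSP's
# complete-deletion default, so absolute pi values need not match tools
# using that policy.

TRANSITION_PAIRS <- matrix(c(1L, 3L, 3L, 1L, 2L, 4L, 4L, 2L), ncol = 2, byrow = TRUE)

# All-pairs site counts via indicator cross-products. enc is the integer
# encoding (A=1..T=4, NA for gap/ambiguity), taxa in rows. Returns n x n
# matrices: compared sites, matches, transitions, transversions.
pair_counts <- function(enc) {
  n <- nrow(enc)
  tE <- t(enc)
  valid <- !is.na(tE)
  storage.mode(valid) <- "double"
  compared <- crossprod(valid)
  ind <- lapply(1:4, function(b) {
    m <- tE == b
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  })
  same <- matrix(0, n, n)
  for (b in 1:4) same <- same + crossprod(ind[[b]])
  ts <- crossprod(ind[[1]], ind[[3]]) + crossprod(ind[[3]], ind[[1]]) +
    crossprod(ind[[2]], ind[[4]]) + crossprod(ind[[4]], ind[[2]])
  list(compared = compared, same = same, ts = ts,
       tv = compared - same - ts)
}

# ---------------------------------------------------------------------------

#' Site-class counts of an alignment
#'
#' Per column, gaps and ambiguity codes are excluded before counting
#' states. A column is variable iff at least two distinct unambiguous
#' states remain, and parsimony informative iff at least two states are
#' each carried by at least two taxa. `gap_sites` counts columns with at
#' least one gap character.
#'
#' @param aln A [dna_alignment()].
#' @return One-row tibble: `aligned_length`, `variable_sites`,
#'   `parsimony_informative_sites`, `gap_sites`, `mean_ungapped_length`,
#'   `min_ungapped_length`, `max_ungapped_length`.
#' @export
site_classes <- function(aln) {
  if (ncol(aln) == 0L) stop("site_classes(): zero-width alignment")
  enc <- encode_alignment(aln)
  counts <- vapply(1:4, function(b) colSums(enc == b, na.rm = TRUE),
                   numeric(ncol(aln)))
  if (ncol(aln) == 1L) counts <- matrix(counts, nrow = 1L)
  nstates <- rowSums(counts > 0)
  variable <- nstates >= 2
  pis <- rowSums(counts >= 2) >= 2
  gap_cols <- colSums(unclass(aln) == "-") > 0
  ungapped <- rowSums(unclass(aln) != "-")
  tibble::tibble(
    aligned_length = ncol(aln),
    variable_sites = sum(variable),
    parsimony_informative_sites = sum(pis),
    gap_sites = sum(gap_cols),
    mean_ungapped_length = mean(ungapped),
    min_ungapped_length = min(ungapped),
    max_ungapped_length = max(ungapped)
  )
}

# ---------------------------------------------------------------------------

k80_from_pq <- function(P, Q) {
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (a <= 0 || b <= 0) return(NA_real_)
  -0.5 * log(a) - 0.25 * log(b)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Sites where either sequence carries a gap or an ambiguity code are
#' excluded (pairwise deletion). With transition proportion P and
#' transversion proportion Q over the L compared sites,
#' d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q).
#'
#' @param x,y Aligned DNA strings of equal length (or two rows of a
#'   [dna_alignment()]).
#' @return Distance in substitutions/site. Errors if no sites are
#'   comparable, or (condition class `plastomarker_saturation`) if the
#'   divergence saturates the model's domain.
#' @export
k80_distance <- function(x, y) {
  cx <- match(chars(toupper(x)), c("A", "C", "G", "T"))
  cy <- match(chars(toupper(y)), c("A", "C", "G", "T"))
  if (length(cx) != length(cy)) stop("sequences must have equal aligned length")
  ok <- !is.na(cx) & !is.na(cy)
  L <- sum(ok)
  if (L == 0L) stop("k80_distance(): no comparable sites")
  diff <- ok & cx != cy
  is_ts <- diff & (((cx == 1L | cx == 3L) & (cy == 1L | cy == 3L)) |
                     ((cx == 2L | cx == 4L) & (cy == 2L | cy == 4L)))
  P <- sum(is_ts) / L
  Q <- (sum(diff) - sum(is_ts)) / L
  d <- k80_from_pq(P, Q)
  if (is.na(d)) {
    rlang::abort(
      sprintf("K80 distance undefined (saturated): P = %.4f, Q = %.4f", P, Q),
      class = "plastomarker_saturation"
    )
  }
  d
}

#' Mean pairwise K80 distance of an alignment
#'
#' Arithmetic mean over all unordered pairs with a defined distance;
#' saturated or incomparable pairs are dropped from the mean rather than
#' imputed.
#'
#' @param aln A [dna_alignment()].
#' @return Mean distance, or `NA` (with a warning) if no pair is defined.
#' @export
mean_k80 <- function(aln) {
  pc <- pair_counts(encode_alignment(aln))
  n <- nrow(aln)
  ut <- upper.tri(pc$compared)
  L <- pc$compared[ut]
  P <- ifelse(L > 0, pc$ts[ut] / L, NA_real_)
  Q <- ifelse(L > 0, pc$tv[ut] / L, NA_real_)
  d <- mapply(function(p, q) if (is.na(p)) NA_real_ else k80_from_pq(p, q), P, Q)
  if (all(is.na(d))) {
    warning("mean_k80(): every pair saturated or incomparable")
    return(NA_real_)
  }
  mean(d, na.rm = TRUE)
}

#' Pairwise K80 distance matrix
#'
#' Feeds the neighbor-joining engine. Saturated pairs are imputed as
#' twice the maximum defined distance (with a warning); a pair with no
#' comparable sites at all is an error.
#'
#' @param aln A [dna_alignment()] with at least 3 taxa.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
distance_matrix <- function(aln) {
  if (nrow(aln) < 3L) stop("distance_matrix(): need at least 3 taxa")
  pc <- pair_counts(encode_alignment(aln))
  n <- nrow(aln)
  if (any(pc$compared[upper.tri(pc$compared)] == 0)) {
    stop("distance_matrix(): a pair of taxa shares no comparable sites")
  }
  P <- pc$ts / pc$compared
  Q <- pc$tv / pc$compared
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  D <- matrix(NA_real_, n, n, dimnames = list(rownames(aln), rownames(aln)))
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

# ---------------------------------------------------------------------------

#' Nucleotide diversity
#'
#' pi = mean over unordered sequence pairs of (pairwise differences /
#' pairwise compared sites), with pairwise deletion of gapped or
#' ambiguous sites.
#'
#' @param aln A [dna_alignment()].
#' @return pi in `[0, 1]`, or `NA` if no pair has comparable sites.
#' @export
nucleotide_diversity <- function(aln) {
  pc <- pair_counts(encode_alignment(aln))
  ut <- upper.tri(pc$compared)
  L <- pc$compared[ut]
  if (all(L == 0)) return(NA_real_)
  diffs <- (pc$compared - pc$same)[ut]
  mean(diffs[L > 0] / L[L > 0])
}

#' Sliding-window nucleotide diversity
#'
#' Windows start at columns 0, `step`, 2*`step`, ... while they fit
#' entirely inside the alignment; the trailing partial window is
#' dropped. If the alignment is narrower than one window, a single
#' whole-alignment window is returned with a warning.
#'
#' @param aln A [dna_alignment()].
#' @param window Window length in alignment columns (default 800).
#' @param step Step size in columns (default 200).
#' @param cmap Optional column map; when given, each window also carries
#'   the 0-based reference position of its start.
#' @return A `pi_track` tibble: `start` (0-based column), `midpoint`,
#'   `pi`, and `ref_start` when `cmap` is supplied.
#' @export
sliding_window_pi <- function(aln, window = 800L, step = 200L, cmap = NULL) {
  w <- ncol(aln)
  enc <- encode_alignment(aln)
  if (w < window) {
    warning("alignment narrower than one window; returning a single whole-alignment window")
    starts <- 0L
    window <- w
  } else {
    starts <- seq.int(0L, w - window, by = step)
  }
  pi_of <- function(s) {
    sub <- enc[, (s + 1L):(s + window), drop = FALSE]
    pc <- pair_counts(sub)
    ut <- upper.tri(pc$compared)
    L <- pc$compared[ut]
    if (all(L == 0)) return(NA_real_)
    diffs <- (pc$compared - pc$same)[ut]
    mean(diffs[L > 0] / L[L > 0])
  }
  out <- tibble::tibble(
    start = starts,
    midpoint = starts + window / 2,
    pi = vapply(starts, pi_of, numeric(1))
  )
  if (!is.null(cmap)) {
    # reference position of the first reference residue at/after each start
    out$ref_start <- vapply(out$start, function(s) {
      i <- which(cmap$map >= s)
      if (length(i) == 0) NA_integer_ else i[1] - 1L
    }, integer(1))
  }
  structure(out, class = c("pi_track", class(out)),
            window = window, step = step)
}
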