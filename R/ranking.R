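# Per-marker metric bundle and the weighted relative-value ranking that
# orders markers by phylogenetic information, plus top-k selection and
# the size filter feeding primer design.

#' Compute the per-marker metric bundle
#'
#' For each marker: mean/min/max ungapped length, aligned length,
#' variable sites, parsimony informative sites, gap sites, mean pairwise
#' K80 distance, and — when the marker retains at least 4 taxa with data
#' — an NJ + bootstrap tree, its mean support, and the RF distance to
#' the reference tree pruned to the marker's leaf set. Taxa whose marker
#' row is entirely gaps are dropped before tree building; markers with
#' fewer than 4 remaining taxa are flagged unusable (trees on < 4 taxa
#' have no internal edges).
#'
#' @param aln The full [dna_alignment()].
#' @param markers Tibble from [partition_markers()].
#' @param reference_tree Optional ape `phylo` to measure RF distance
#'   against (typically the full-plastome tree).
#' @param B Bootstrap replicates per marker (default 100).
#' @param seed Integer seed; each marker draws from its own substream.
#' @return Tibble with one row per marker: `marker`, `class`, `n_taxa`,
#'   `bp_mean`, `bp_min`, `bp_max`, `aligned_bp`, `variable_sites`,
#'   `pis`, `gap_sites`, `mean_k80`, `mean_bootstrap`, `tree_distance`,
#'   `usable`, `tree` (list-column).
#' @export
marker_metrics <- function(aln, markers, reference_tree = NULL,
                           B = 100L, seed = 1L) {
  rows <- purrr::map(seq_len(nrow(markers)), function(i) {
    sub <- extract_marker(aln, markers[i, ])
    has_data <- rowSums(unclass(sub) != "-") > 0
    kept <- sub[has_data, , drop = FALSE]
    class(kept) <- c("dna_alignment", "matrix", "array")
    n_taxa <- nrow(kept)
    usable <- n_taxa >= 4L
    sc <- if (n_taxa >= 2L) site_classes(kept) else NULL
    mk <- if (n_taxa >= 2L) {
      tryCatch(suppressWarnings(mean_k80(kept)), error = function(e) NA_real_)
    } else NA_real_
    tree <- NULL
    bs <- NA_real_
    rf <- NA_real_
    if (usable) {
      tree <- tryCatch(
        suppressWarnings(bootstrap_support(kept, B = B,
                                           seed = substream_seed(seed, 10000L + i))),
        error = function(e) NULL
      )
      if (!is.null(tree)) {
        bs <- mean_support(tree)
        if (!is.null(reference_tree)) {
          rf <- tryCatch(
            rf_distance(tree, prune_to_leaves(reference_tree, tree$tip.label)),
            error = function(e) NA_real_
          )
        }
      } else {
        usable <- FALSE
      }
    }
    tibble::tibble(
      marker = markers$marker[i],
      class = markers$class[i],
      n_taxa = n_taxa,
      bp_mean = if (is.null(sc)) NA_real_ else sc$mean_ungapped_length,
      bp_min = if (is.null(sc)) NA_integer_ else sc$min_ungapped_length,
      bp_max = if (is.null(sc)) NA_integer_ else sc$max_ungapped_length,
      aligned_bp = ncol(sub),
      variable_sites = if (is.null(sc)) NA_integer_ else sc$variable_sites,
      pis = if (is.null(sc)) NA_integer_ else sc$parsimony_informative_sites,
      gap_sites = if (is.null(sc)) NA_integer_ else sc$gap_sites,
      mean_k80 = mk,
      mean_bootstrap = bs,
      tree_distance = rf,
      usable = usable,
      tree = list(tree)
    )
  })
  dplyr::bind_rows(rows)
}

#' Rank markers by weighted relative information value
#'
#' Each metric is rescaled to `[0, 1]` by min-max normalization over the
#' ranked set (or over explicitly supplied bounds): variable sites and
#' mean bootstrap directly, tree distance inverted so that a *smaller*
#' distance to the reference tree scores higher. The score is the
#' weighted mean (default weights 1 for variable sites, 2 for bootstrap,
#' 3 for tree distance); ranks are dense in descending score, with ties
#' broken by raw variable sites then marker name.
#'
#' @param metrics Tibble with columns `marker`, `variable_sites`,
#'   `mean_bootstrap`, `tree_distance` (e.g. from [marker_metrics()]).
#'   Rows missing any of the three metrics are excluded with a warning.
#' @param weights Numeric length-3 vector `(variable, bootstrap,
#'   distance)`, all positive.
#' @param bounds Optional list with elements `variable`, `bootstrap`,
#'   `distance`, each `c(min, max)`, fixing the normalization ranges
#'   (e.g. the global ranges of a larger survey the ranked subset came
#'   from). Ranges not supplied are taken from the data.
#' @return A `marker_ranking` tibble: input columns plus `r_var`,
#'   `r_bs`, `r_dist`, `score`, `rank`, ordered best first.
#' @export
rank_markers <- function(metrics, weights = c(1, 2, 3), bounds = NULL) {
  stopifnot(length(weights) == 3, all(weights > 0))
  keep <- !is.na(metrics$variable_sites) & !is.na(metrics$mean_bootstrap) &
    !is.na(metrics$tree_distance)
  if ("usable" %in% names(metrics)) keep <- keep & metrics$usable
  if (any(!keep)) {
    warning(sum(!keep), " marker(s) lacking metrics excluded from ranking")
  }
  m <- metrics[keep, , drop = FALSE]
  if (nrow(m) < 2L) stop("rank_markers(): need at least 2 markers with all metrics")
  rng <- function(v, nm) {
    if (!is.null(bounds) && !is.null(bounds[[nm]])) bounds[[nm]] else range(v)
  }
  rel <- function(v, r) {
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
  }
  rv <- rng(m$variable_sites, "variable")
  rb <- rng(m$mean_bootstrap, "bootstrap")
  rd <- rng(m$tree_distance, "distance")
  m$r_var <- rel(m$variable_sites, rv)
  m$r_bs <- rel(m$mean_bootstrap, rb)
  m$r_dist <- if (diff(rd) == 0) rep(0, nrow(m)) else (rd[2] - m$tree_distance) / (rd[2] - rd[1])
  m$score <- (weights[1] * m$r_var + weights[2] * m$r_bs + weights[3] * m$r_dist) /
    sum(weights)
  m <- dplyr::arrange(m, dplyr::desc(.data$score),
                      dplyr::desc(.data$variable_sites), .data$marker)
  m$rank <- dplyr::dense_rank(dplyr::desc(m$score))
  structure(m, class = c("marker_ranking", class(m)),
            weights = weights, bounds = list(variable = rv, bootstrap = rb, distance = rd))
}

#' Top-k markers of a ranking
#'
#' @param ranked A `marker_ranking` from [rank_markers()].
#' @param k Number of markers (<= number ranked).
#' @return Character vector of marker names, best first.
#' @export
select_top <- function(ranked, k) {
  if (k > nrow(ranked)) stop("select_top(): k exceeds the number of ranked markers")
  ranked$marker[seq_len(k)]
}

#' Filter markers by mean ungapped length
#'
#' Keeps markers short enough for single-pass PCR/Sanger work.
#'
#' @param metrics Tibble with `bp_mean` (e.g. from [marker_metrics()]).
#' @param max_len Length threshold in bp (default 900; markers with
#'   `bp_mean < max_len` are kept).
#' @return The filtered tibble.
#' @export
size_filter <- function(metrics, max_len = 900) {
  dplyr::filter(metrics, !is.na(.data$bp_mean), .data$bp_mean < max_len)
}
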