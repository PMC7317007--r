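# broom-style accessors for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a marker ranking
#'
#' @param x A `marker_ranking` from [rank_markers()].
#' @param ... Ignored.
#' @return A plain tibble of the ranking's core columns.
#' @export
tidy.marker_ranking <- function(x, ...) {
  keep <- intersect(c("rank", "marker", "class", "variable_sites",
                      "mean_bootstrap", "tree_distance", "r_var", "r_bs",
                      "r_dist", "score"), names(x))
  tibble::as_tibble(x)[, keep]
}

#' @rdname tidy.marker_ranking
#' @export
glance.marker_ranking <- function(x, ...) {
  w <- attr(x, "weights")
  tibble::tibble(
    n_markers = nrow(x),
    best_marker = x$marker[1],
    best_score = x$score[1],
    score_range = diff(range(x$score)),
    weight_variable = w[1], weight_bootstrap = w[2], weight_distance = w[3]
  )
}

#' Tidy a diversity track
#'
#' @param x A `pi_track` from [sliding_window_pi()].
#' @param ... Ignored.
#' @return A plain tibble of windows.
#' @export
tidy.pi_track <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.pi_track
#' @export
glance.pi_track <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x),
    window = attr(x, "window"),
    step = attr(x, "step"),
    pi_mean = mean(x$pi, na.rm = TRUE),
    pi_min = min(x$pi, na.rm = TRUE),
    pi_max = max(x$pi, na.rm = TRUE)
  )
}
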