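# ggplot2 methods for the two result types people actually look at:
# the sliding-window diversity track and the marker ranking.

#' Plot a sliding-window nucleotide diversity track
#'
#' @param object A `pi_track` from [sliding_window_pi()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pi_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$midpoint, y = .data$pi)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "alignment position (window midpoint)",
      y = expression(pi),
      title = sprintf("Sliding-window nucleotide diversity (window %d, step %d)",
                      attr(object, "window"), attr(object, "step"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a marker ranking
#'
#' Bar chart of the weighted relative-value scores, best marker on top,
#' filled by marker class.
#'
#' @param object A `marker_ranking` from [rank_markers()].
#' @param top Show at most this many markers (default 20).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.marker_ranking <- function(object, top = 20L, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  df$marker <- factor(df$marker, levels = rev(df$marker))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$marker))
  if ("class" %in% names(df)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$class))
  } else {
    p <- p + ggplot2::geom_col()
  }
  p +
    ggplot2::labs(x = "weighted relative information score", y = NULL,
                  fill = "class") +
    ggplot2::theme_minimal()
}
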