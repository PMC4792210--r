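#' Score versus mean distance scatter plot
#'
#' The classic DSA overview: one point per pair, DSA score against mean
#' Cα-Cα distance, intrahelical pairs red and interhelical blue. Infinite
#' scores cannot be drawn and are dropped with a message.
#'
#' @param object A `dsa` fit (for `autoplot`) or a score-distance table from
#'   [score_distance_table()] (for `plot_score_distance`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_score_distance <- function(object, ...) {
  tbl <- if (inherits(object, "dsa")) score_distance_table(object$stats) else object
  inf <- !is.finite(tbl$score)
  if (any(inf)) {
    rlang::inform(sprintf("Dropping %d infinite-score pair(s) from the scatter",
                          sum(inf)))
    tbl <- tbl[!inf, ]
  }
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$mean, y = .data$score,
                                    colour = .data$class)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(intra = "red", inter = "blue"),
      labels = c(intra = "intrahelical", inter = "interhelical"),
      name = NULL) +
    ggplot2::labs(x = "mean Cα-Cα distance (Å)",
                  y = "DSA score (mean / sd)") +
    ggplot2::theme_classic()
}

#' @rdname plot_score_distance
#' @importFrom ggplot2 autoplot
#' @export
autoplot.dsa <- function(object, ...) plot_score_distance(object, ...)

#' Seven-helix colour scheme
#'
#' Fixed palette for per-helix curves: purple (A) through blue, cyan, green,
#' yellow, orange to red (G).
#'
#' @return Named character vector of colours, names `"A"` to `"G"`.
#' @export
helix_colors <- function() {
  c(A = "purple", B = "blue", C = "cyan", D = "green",
    E = "yellow3", F = "orange", G = "red")
}

#' Cumulative-ratio curves plot
#'
#' Per-group cumulative ratio of pairs over the top ranks (one curve per
#' helix or helix pair). Helix groups use the fixed seven-colour scheme of
#' [helix_colors()].
#'
#' @param curves Tibble from [cumulative_ratio()].
#' @return A ggplot object.
#' @export
plot_cumulative_ratio <- function(curves) {
  groups <- unique(curves$group)
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$rank, y = .data$ratio,
                                            colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.5) +
    ggplot2::labs(x = "rank", y = "cumulative ratio of pairs", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_classic()
  if (all(groups %in% names(helix_colors()))) {
    p <- p + ggplot2::scale_colour_manual(values = helix_colors())
  }
  p
}
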