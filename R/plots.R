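#' Plot a fitted leaf-mine incidence curve
#'
#' Draws the fitted logistic incidence curve p(TIV) and, when the
#' fitting data are supplied, the observed 0/1 presences.
#'
#' @param object A `mine_fit` object.
#' @param data Optional tibble with `tiv` and `mined` to overlay.
#' @param n_grid Curve resolution.
#' @param xmax Upper end of the TIV grid (defaults to the data maximum
#'   or 1000).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mine_fit <- function(object, data = NULL, n_grid = 201,
                              xmax = NULL, ...) {
  xmax <- xmax %||% if (!is.null(data)) max(data$tiv) else 1000
  curve <- incidence_curve(object, seq(0, xmax, length.out = n_grid))
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$tiv, y = .data$p)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::labs(x = "Total importance value (per-mille scale)",
                  y = "Leaf-mine incidence probability",
                  title = sprintf("%s fit", object$model)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data, ggplot2::aes(x = .data$tiv, y = .data$mined),
      alpha = 0.3, shape = 16)
  }
  p
}

#' Plot host ratios across dominance rank groups
#'
#' @param object A `host_ratio_table`.
#' @param ... Unused.
#' @return A ggplot bar chart of host ratio by rank group.
#' @export
autoplot.host_ratio_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$rank),
                                       y = .data$host_ratio)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::labs(x = "Dominance rank group (1 = most dominant)",
                  y = "Leafminer host ratio",
                  title = sprintf("Host ratio by %s dominance group",
                                  attr(object, "level"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
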