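#' Plot a partition in the MDS plane
#'
#' @param object a `group_partition`.
#' @param mds an `mds_result` over the same cells (2-D).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot group_partition
#' @export
autoplot.group_partition <- function(object, mds, ...) {
  stopifnot(inherits(mds, "mds_result"))
  df <- tidy(mds)
  assign <- tidy(object)
  df <- dplyr::left_join(df, assign, by = c(item = "node"))
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                   colour = factor(.data$group),
                                   shape = .data$residual)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2", colour = "group",
                  shape = "residual") +
    ggplot2::theme_minimal()
}

#' Heat map of group-by-regime enrichment fractions
#'
#' @param object an `enrichment_table`.
#' @param ... unused.
#' @return A ggplot: tiles of the fraction of each group in each regime per
#'   pair, significant entries outlined.
#' @method autoplot enrichment_table
#' @export
autoplot.enrichment_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$regime, factor(.data$group),
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$significant, ], fill = NA,
                       colour = "black", linewidth = 0.8) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "signaling regime", y = "group",
                  fill = "fraction of group") +
    ggplot2::theme_minimal()
}

#' Bivariate regime plot for one ligand-receptor pair
#'
#' Scatter of ligand vs receptor normalized expression with the four sign
#' quadrants (paracrine source/target, autocrine, none) annotated.
#'
#' @param regimes output of [classify_regime()].
#' @param pair display name of the pair to plot.
#' @return A ggplot.
#' @export
plot_regimes <- function(regimes, pair) {
  df <- regimes[regimes$pair == pair & !regimes$missing, ]
  if (!nrow(df)) stop("no complete data for pair ", pair, call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(.data$ligand_value, .data$receptor_value,
                                   colour = .data$regime)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(title = pair, x = "ligand (-ddCt)", y = "receptor (-ddCt)") +
    ggplot2::theme_minimal()
}

#' Circular layout plot of a group-interaction network
#'
#' @param object an `interaction_network`.
#' @param ... unused.
#' @return A ggplot with directed edges drawn between groups on a circle;
#'   autocrine interactions shown as labelled loops at the node.
#' @method autoplot interaction_network
#' @export
autoplot.interaction_network <- function(object, ...) {
  nodes <- object$nodes
  n <- nrow(nodes)
  theta <- 2 * pi * (seq_len(n) - 1) / max(n, 1)
  layout <- tibble::tibble(group = nodes$group, x = cos(theta), y = sin(theta),
                           size = nodes$size)
  edges <- object$edges
  para <- edges[edges$type == "paracrine", ]
  auto <- edges[edges$type == "autocrine", ]
  para <- dplyr::left_join(para, layout, by = c(from = "group")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(layout, by = c(to = "group")) |>
    dplyr::rename(x1 = "x", y1 = "y")
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(.data$x, .data$y, size = .data$size),
                        colour = "steelblue") +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(.data$x, .data$y, label = .data$group),
                       nudge_y = 0.15) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (nrow(para)) {
    p <- p + ggplot2::geom_curve(
      data = para,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   linewidth = .data$weight),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "in")),
      curvature = 0.2, alpha = 0.7
    )
  }
  if (nrow(auto)) {
    auto <- dplyr::left_join(auto, layout, by = c(from = "group"))
    p <- p + ggplot2::geom_text(
      data = auto,
      ggplot2::aes(.data$x, .data$y, label = paste0("↺ ", .data$pair)),
      nudge_y = -0.2, size = 3
    )
  }
  p + ggplot2::scale_linewidth(range = c(0.3, 2), limits = c(0, 1))
}
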