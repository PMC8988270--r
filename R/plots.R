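#' Plot a symptom network
#'
#' Nodes at fixed (e.g. group-average) coordinates, edges drawn with width
#' proportional to the absolute partial correlation, blue for positive and
#' red for negative weights, nodes coloured by symptom category when item
#' metadata are supplied.
#'
#' @param object A `symptom_network`.
#' @param layout Optional p x 2 coordinate matrix (see [average_layout()]);
#'   computed from the network itself when missing.
#' @param items Optional item metadata tibble like [bdi_items()].
#' @param seed Seed for the layout when it has to be computed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.symptom_network <- function(object, layout = NULL, items = NULL,
                                     seed = 1, ...) {
  if (is.null(layout)) layout <- average_layout(object, seed = seed)
  edges <- tidy(object)
  ed <- dplyr::mutate(
    edges,
    x = layout[.data$item_i, 1], y = layout[.data$item_i, 2],
    xend = layout[.data$item_j, 1], yend = layout[.data$item_j, 2],
    sign = ifelse(.data$weight >= 0, "positive", "negative")
  )
  nodes <- tibble::tibble(
    item = seq_len(object$p), x = layout[, 1], y = layout[, 2]
  )
  if (!is.null(items) && nrow(items) == object$p) {
    nodes$category <- items$category
  } else {
    nodes$category <- "item"
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = abs(.data$weight),
                   colour = .data$sign),
      alpha = 0.7
    ) +
    ggplot2::scale_colour_manual(
      values = c(positive = "#2166ac", negative = "#b2182b")
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$category),
      shape = 21, size = 7, colour = "grey20"
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$item), size = 3
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "edge sign", fill = "category")
}

#' Plot standardized centralities by group
#'
#' One panel per centrality measure, z-scores on the x axis, items on the y
#' axis, one line per group.
#'
#' @param centrality Long-format table from [centrality_by_group()].
#' @return A ggplot object.
#' @export
plot_centrality <- function(centrality) {
  stopifnot(all(c("group", "item", "measure", "z") %in% names(centrality)))
  centrality$item <- factor(centrality$item,
                            levels = rev(unique(centrality$item)))
  ggplot2::ggplot(
    centrality,
    ggplot2::aes(x = .data$z, y = .data$item, colour = .data$group,
                 group = .data$group)
  ) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure, nrow = 1) +
    ggplot2::labs(x = "standardized z-score", y = NULL, colour = "group") +
    ggplot2::theme_minimal()
}

#' Plot bootstrapped edge-weight confidence intervals
#'
#' Edges ordered by sample weight (descending), sample estimate in red,
#' bootstrap mean in black, percentile CI as a grey ribbon.
#'
#' @param object An `edge_bootstrap` tibble from [bootstrap_edges()].
#' @param max_edges Show at most this many of the strongest edges.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edge_bootstrap <- function(object, max_edges = 50, ...) {
  df <- utils::head(as.data.frame(object), max_edges)
  df$edge <- factor(
    paste0(df$item_i, "-", df$item_j),
    levels = rev(paste0(df$item_i, "-", df$item_j))
  )
  ggplot2::ggplot(df, ggplot2::aes(y = .data$edge)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper,
                   group = 1),
      fill = "grey80"
    ) +
    ggplot2::geom_path(ggplot2::aes(x = .data$boot_mean, group = 1),
                       colour = "black") +
    ggplot2::geom_path(ggplot2::aes(x = .data$sample, group = 1),
                       colour = "red") +
    ggplot2::labs(x = "edge weight (partial correlation)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot case-dropping stability curves
#'
#' Mean subsample-to-full-sample centrality correlation against the drop
#' proportion, per measure.
#'
#' @param object A `case_drop_result` from [case_dropping()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.case_drop_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$q, y = .data$mean_correlation,
                 colour = .data$measure)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.7, linetype = "dashed") +
    ggplot2::labs(x = "proportion of cases dropped",
                  y = "correlation with full-sample centrality") +
    ggplot2::theme_minimal()
}
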