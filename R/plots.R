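#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Score plot of two principal components
#'
#' Samples plotted in the plane of two components (default PC3 vs PC4)
#' coloured by design cell, with per-group 95% confidence ellipses.
#'
#' @param object A `pc_model`.
#' @param components Pair of component indices.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pc_model
#' @export
autoplot.pc_model <- function(object, components = c(3, 4), ...) {
  design <- object$design
  df <- tibble::tibble(
    sample_id = rownames(object$scores),
    x = object$scores[, components[1]],
    y = object$scores[, components[2]]
  )
  df <- dplyr::left_join(df, design[, c("sample_id", "group")], by = "sample_id")
  ell <- score_ellipses(object, components)
  theta <- seq(0, 2 * pi, length.out = 120)
  ell_pts <- purrr::pmap_dfr(
    ell[, c("group", "center_x", "center_y", "a", "b", "angle_rad")],
    function(group, center_x, center_y, a, b, angle_rad) {
      xs <- a * cos(theta); ys <- b * sin(theta)
      tibble::tibble(
        group = group,
        x = center_x + xs * cos(angle_rad) - ys * sin(angle_rad),
        y = center_y + xs * sin(angle_rad) + ys * cos(angle_rad))
    })
  pct <- round(100 * object$variance_fraction[components], 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$group)) +
    ggplot2::geom_path(data = ell_pts, ggplot2::aes(group = .data$group),
                       linewidth = 0.3) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("t%d (%.1f%%)", components[1], pct[1]),
                  y = sprintf("t%d (%.1f%%)", components[2], pct[2]),
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Interaction heatmap of scaled quantities
#'
#' Tile heatmap of standard-scaled protein quantities, rows in
#' dendrogram leaf order and annotated by the first-branch cluster,
#' columns fixed in design order.
#'
#' @param plot_data Bundle from [export_plot_data()].
#' @return A ggplot.
#' @export
plot_interaction_heatmap <- function(plot_data) {
  heat <- plot_data$heatmap
  heat$protein_id <- stats::reorder(heat$protein_id, heat$row_order)
  heat$sample_id <- factor(heat$sample_id, unique(heat$sample_id))
  ggplot2::ggplot(heat, ggplot2::aes(x = .data$sample_id,
                                     y = .data$protein_id,
                                     fill = .data$log2_quantity)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#8c510a") +
    ggplot2::labs(x = NULL, y = NULL, fill = "scaled\nlog2") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90))
}

#' Per-protein group boxplots
#'
#' Boxplots of log2 quantities by design cell for a handful of
#' proteins, drawn from precomputed five-number summaries.
#'
#' @param plot_data Bundle from [export_plot_data()].
#' @param proteins Protein identifiers to show (default first 6).
#' @return A ggplot.
#' @export
plot_protein_boxplots <- function(plot_data, proteins = NULL) {
  box <- plot_data$boxplots
  if (is.null(proteins)) proteins <- utils::head(unique(box$protein_id), 6)
  box <- box[box$protein_id %in% proteins, ]
  ggplot2::ggplot(box, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_boxplot(ggplot2::aes(ymin = .data$lower_whisker,
                                       lower = .data$q1,
                                       middle = .data$median,
                                       upper = .data$q3,
                                       ymax = .data$upper_whisker,
                                       fill = .data$group),
                          stat = "identity") +
    ggplot2::facet_wrap(ggplot2::vars(.data$protein_id), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "log2 quantity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
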