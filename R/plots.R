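grid_tile_plot <- function(df, fill, title, legend) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col + 0.5 * ((.data$row - 1) %% 2),
                                   y = .data$row, fill = {{ fill }})) +
    ggplot2::geom_point(shape = 21, size = 6, colour = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = title, x = "neuron column", y = "neuron row",
                  fill = legend) +
    ggplot2::theme_minimal()
}

#' Plot a fitted SOM
#'
#' Map diagnostics: `"umatrix"` shades each neuron by its mean weight-space
#' distance to its lattice neighbors (dark ridges mark cluster
#' boundaries), `"hits"` shows the per-neuron sample counts, and
#' `"planes"` shows one weight plane per input feature (visually similar
#' planes indicate correlated features).
#'
#' @param object A `sway_som` model.
#' @param type `"umatrix"`, `"hits"` or `"planes"`.
#' @param data Samples for the hit counts (required for `type = "hits"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot sway_som
autoplot.sway_som <- function(object, type = c("umatrix", "hits", "planes"),
                              data = NULL, ...) {
  type <- match.arg(type)
  if (type == "umatrix") {
    grid_tile_plot(som_umatrix(object), .data$distance,
                   "Neighborhood distance (U-matrix)", "distance")
  } else if (type == "hits") {
    if (is.null(data)) stop("`data` is required for the hit map")
    grid_tile_plot(som_hits(object, data), .data$hits,
                   "Input vector hits", "hits")
  } else {
    grid_tile_plot(som_weight_planes(object), .data$weight,
                   "Weight planes", "weight") +
      ggplot2::facet_wrap(~ .data$feature)
  }
}

#' Plot a Davies-Bouldin scan
#'
#' Mean DB index against the candidate cluster count with the local minima
#' highlighted; the chosen K sits at the minimum with the highest
#' F-measure.
#'
#' @param object A `db_scan` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot db_scan
autoplot.db_scan <- function(object, ...) {
  df <- tidy.db_scan(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$mean_db)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_minimum), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "number of clusters K", y = "mean DB index",
                  colour = "local minimum") +
    ggplot2::theme_minimal()
}

#' Plot a study evaluation
#'
#' Median external measures per condition pair, split by sway direction,
#' mirroring the per-pair bar summaries of a between-condition analysis.
#'
#' @param object A `sway_eval` from [run_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot sway_eval
autoplot.sway_eval <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$measure, .data$median,
                               fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$median - .data$iqr / 2,
                   ymax = .data$median + .data$iqr / 2),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::facet_wrap(~ .data$pair) +
    ggplot2::labs(x = NULL, y = "median (bar) ± IQR/2",
                  fill = "direction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot a sway path or recording trace
#'
#' Ground-projected sway path (`dy_cm` against `dx_cm`, i.e. AP against
#' ML) of a generated path tibble.
#'
#' @param path Tibble with `dx_cm`, `dy_cm` columns
#'   ([generate_sway_path()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_sway_path <- function(path, ...) {
  ggplot2::ggplot(path, ggplot2::aes(.data$dx_cm, .data$dy_cm)) +
    ggplot2::geom_path(alpha = 0.6, colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ML displacement (cm)", y = "AP displacement (cm)") +
    ggplot2::theme_minimal()
}
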