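#' Plot a per-vertex scalar map over a surface (x-y projection)
#'
#' Handy for synthetic sheets and quick quality checks of morph maps,
#' labels or predicted probabilities.
#'
#' @param surface a [cortical_surface()].
#' @param values per-vertex numeric vector (e.g. `morph$sulc`, labels,
#'   probabilities).
#' @param name legend title.
#' @return a ggplot object.
#' @export
plot_surface_map <- function(surface, values, name = "value") {
  df <- tibble::tibble(x = surface$vertices[, 1], y = surface$vertices[, 2],
                       value = as.numeric(values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_viridis_c(name = name) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_centroids
#' @param object a `centroid_set`.
#' @param ... passed on to [plot_centroids()].
#' @export
autoplot.centroid_set <- function(object, ...) plot_centroids(object, ...)

#' @rdname plot_training
#' @param object a `hinge3_model`.
#' @param ... unused.
#' @export
autoplot.hinge3_model <- function(object, ...) plot_training(object)

#' Plot per-subject evaluation metrics
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return a ggplot object: per-subject-hemisphere precision/recall/F1 bars.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$per_subject[, c("subject_id", "hemisphere", "precision",
                           "recall", "f1")],
    cols = c("precision", "recall", "f1"),
    names_to = "metric", values_to = "pct")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject_id, y = .data$pct,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~hemisphere) +
    ggplot2::labs(y = "percent", x = NULL,
                  title = "3-hinge region identification") +
    ggplot2::theme_minimal()
}
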