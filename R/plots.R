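# ggplot2 displays: axial slice montages for maps, the Monte-Carlo null
# distribution, and correlation scatter plots.

map_slice_data <- function(map, slices) {
  d <- map$grid$dims
  if (is.null(slices)) slices <- unique(round(seq(2, d[3] - 1, length.out = 6)))
  rows <- lapply(slices, function(k) {
    g <- expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1))
    mm <- voxel_to_mm(map$grid, cbind(g$i, g$j, k - 1))
    tibble::tibble(x = mm[, 1], y = mm[, 2], slice_z = round(mm[1, 3], 1),
                   value = c(map$data[, , k]))
  })
  dplyr::bind_rows(rows)
}

#' Axial slice montage of a scalar map
#'
#' @param object A [scalar_map].
#' @param slices Integer 1-based slice indices (default: 6 evenly spaced).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scalar_map <- function(object, slices = NULL, ...) {
  df <- map_slice_data(object, slices)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice_z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "grey95",
                                  high = "firebrick") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = object$kind) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.scalar_map
#' @export
autoplot.degree_result <- function(object, slices = NULL, ...) {
  autoplot.scalar_map(object$z, slices, ...) +
    ggplot2::labs(fill = paste0("degree z (", object$flavor, ")"))
}

#' Null distribution of maximum cluster sizes
#'
#' Histogram of the simulated maxima with the derived minimum cluster size
#' marked.
#'
#' @param object An `mc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mc_result <- function(object, ...) {
  df <- tibble::tibble(max_size = object$null_max_cluster_sizes)
  ggplot2::ggplot(df, ggplot2::aes(.data$max_size)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = object$min_cluster_size,
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "max null cluster size (voxels)", y = "simulations",
                  subtitle = sprintf("min cluster size = %d (alpha %g)",
                                     object$min_cluster_size,
                                     object$corrected_alpha)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of cluster means against a clinical score
#'
#' @param values Per-patient cluster mean values.
#' @param scores Per-patient clinical scores (same order).
#' @param label Axis label for the score (default "THQ score").
#' @return A ggplot object.
#' @export
plot_cluster_correlation <- function(values, scores, label = "THQ score") {
  df <- tibble::tibble(value = values, score = scores)
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$score)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "cluster mean z", y = label) +
    ggplot2::theme_minimal()
}
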