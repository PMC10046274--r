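#' Plot the nearest-neighbour similarity distribution
#'
#' Histogram of each molecule's similarity to its closest neighbour, with an
#' optional outlier-cutoff line. The shape of this distribution is what the
#' outlier filter acts on: a low-similarity mode marks structurally isolated
#' molecules.
#'
#' @param profile A tibble from [nearest_neighbor_profile()].
#' @param cutoff Optional similarity cutoff to mark.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_nn_profile <- function(profile, cutoff = NULL, bins = 40) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$nn_sim)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40", colour = "white") +
    ggplot2::labs(x = "nearest-neighbour Tanimoto similarity",
                  y = "molecules") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = 2,
                                 colour = "firebrick")
  }
  p
}

#' @export
autoplot.elbow_curve <- function(object, ...) {
  knee <- detect_knee(object)
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$score)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters k", y = object$scoring) +
    ggplot2::theme_minimal()
  if (!is.na(knee)) {
    p <- p + ggplot2::geom_vline(xintercept = knee, linetype = 2,
                                 colour = "firebrick")
  }
  p
}

#' @export
autoplot.umap_grid_search <- function(object, ...) {
  df <- tidyr::pivot_longer(object$results,
                            c("silhouette", "calinski_harabasz",
                              "davies_bouldin"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$min_dist, y = .data$value,
                                   colour = factor(.data$n_neighbors))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(colour = "n_neighbors") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.avg_sim_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster_j),
                                   y = factor(.data$cluster_i),
                                   fill = .data$mean_similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$mean_similarity), "",
                     sprintf("%.3f", .data$mean_similarity))), size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA), na.value = "grey90") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "cluster", y = "cluster",
                  fill = "mean Tanimoto") +
    ggplot2::theme_minimal()
}
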