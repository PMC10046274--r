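#' Grid search over UMAP embedding hyperparameters at fixed k
#'
#' First step of the two-step tuning procedure: for every combination of
#' `n_neighbors` and `min_dist`, embed the fingerprints, cluster the embedding
#' into `fixed_k` agglomerative clusters, and score the result with the three
#' validity indices (computed on the embedding coordinates). Each combination
#' earns a "win" per metric it is best at (max silhouette, max
#' Calinski-Harabasz, min Davies-Bouldin); the winner is the combination with
#' the most wins, ties broken towards the smallest `n_neighbors`, then the
#' smallest `min_dist`. All embeddings are computed in a single toolkit call.
#'
#' @param fps A [fingerprint_set()].
#' @param neighbor_values Vector of `n_neighbors` values.
#' @param min_dist_values Vector of `min_dist` values.
#' @param fixed_k Number of clusters held fixed during the search (>= 2).
#' @param seed Embedding random state (default 42).
#' @return An object of class `umap_grid_search`: list with `results` (one
#'   tibble row per combination, including `wins`) and `winner` (one row).
#' @export
grid_search_umap <- function(fps, neighbor_values, min_dist_values, fixed_k,
                             seed = 42L) {
  if (length(neighbor_values) == 0 || length(min_dist_values) == 0) {
    abort_validation("both hyperparameter grids must be non-empty.")
  }
  if (fixed_k < 2) abort_validation("`fixed_k` must be at least 2.")
  grid <- tidyr::expand_grid(n_neighbors = sort(unique(neighbor_values)),
                             min_dist = sort(unique(min_dist_values)))
  cfgs <- dplyr::mutate(grid, n_components = 2L, metric = "jaccard",
                        seed = seed)
  embeddings <- umap_embed_batch(fps, cfgs)
  results <- purrr::map2_dfr(seq_len(nrow(grid)), embeddings, function(i, emb) {
    row <- grid[i, ]
    scores <- tryCatch({
      cl <- agglomerative_on_embedding(emb, fixed_k)
      quality_report(emb, cl)
    }, error = function(e) NULL)
    if (is.null(scores)) {
      return(dplyr::mutate(row, silhouette = NA_real_,
                           calinski_harabasz = NA_real_,
                           davies_bouldin = NA_real_))
    }
    dplyr::bind_cols(row, scores[, c("silhouette", "calinski_harabasz",
                                     "davies_bouldin")])
  })
  results <- score_wins(results)
  winner <- dplyr::slice(dplyr::arrange(
    dplyr::filter(results, !is.na(.data$silhouette)),
    dplyr::desc(.data$wins), .data$n_neighbors, .data$min_dist), 1)
  structure(list(results = results, winner = winner, fixed_k = fixed_k,
                 seed = seed),
            class = "umap_grid_search")
}

score_wins <- function(results) {
  ok <- !is.na(results$silhouette)
  wins <- integer(nrow(results))
  if (any(ok)) {
    wins <- wins +
      (results$silhouette == max(results$silhouette[ok]) & ok) +
      (results$calinski_harabasz == max(results$calinski_harabasz[ok]) & ok) +
      (results$davies_bouldin == min(results$davies_bouldin[ok]) & ok)
  }
  results$wins <- as.integer(ifelse(ok, wins, NA_integer_))
  results
}

#' @export
print.umap_grid_search <- function(x, ...) {
  cat(sprintf("<umap_grid_search> %d combinations at k = %d\n",
              nrow(x$results), x$fixed_k))
  cat(sprintf("  winner: n_neighbors = %d, min_dist = %.2g (%d of 3 metrics)\n",
              x$winner$n_neighbors, x$winner$min_dist, x$winner$wins))
  invisible(x)
}

#' @export
tidy.umap_grid_search <- function(x, ...) x$results

#' @export
glance.umap_grid_search <- function(x, ...) x$winner

#' Elbow curve over the number of clusters
#'
#' Second tuning step: cluster a fixed feature space (typically one frozen
#' embedding) into each candidate number of clusters and record a score per
#' k. `"distortion"` is the sum of squared Euclidean distances between each
#' observation and the centroid of its assigned cluster (non-increasing in
#' k); `"silhouette"` is the mean silhouette coefficient. The agglomerative
#' tree is built once and cut at every k.
#'
#' @param x A numeric matrix (embedding or feature rows) or a
#'   [fingerprint_set()] (embedded first with the given UMAP settings).
#' @param k_range Increasing vector of cluster numbers, within `[2, n - 1]`.
#' @param scoring `"distortion"` or `"silhouette"`.
#' @param n_neighbors,min_dist,seed Embedding settings, used only when `x` is
#'   a fingerprint set.
#' @return An object of class `elbow_curve`: tibble-backed list with `k`,
#'   `score` and the scoring name.
#' @export
elbow_curve <- function(x, k_range, scoring = c("distortion", "silhouette"),
                        n_neighbors = 15L, min_dist = 0.1, seed = 42L) {
  scoring <- match.arg(scoring)
  if (is_fingerprint_set(x)) {
    x <- umap_embed(x, n_neighbors = n_neighbors, min_dist = min_dist,
                    seed = seed)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  k_range <- as.integer(k_range)
  if (length(k_range) == 0 || is.unsorted(k_range, strictly = TRUE) ||
      min(k_range) < 2 || max(k_range) > n - 1) {
    abort_validation("`k_range` must be strictly increasing within [2, n - 1].")
  }
  tree <- ward_linkage(stats::dist(x))
  score <- vapply(k_range, function(k) {
    labels <- cut_tree(tree, k = k)$labels
    if (scoring == "distortion") {
      centers <- rowsum(x, labels) / tabulate(labels, k)
      sum((x - centers[labels, , drop = FALSE])^2)
    } else {
      silhouette_mean(x, labels)$score
    }
  }, numeric(1))
  structure(list(k = k_range, score = score, scoring = scoring),
            class = "elbow_curve")
}

#' @export
print.elbow_curve <- function(x, ...) {
  knee <- detect_knee(x)
  cat(sprintf("<elbow_curve> %s over k = %d..%d; knee: %s\n", x$scoring,
              min(x$k), max(x$k), ifelse(is.na(knee), "unclear", knee)))
  invisible(x)
}

#' @export
tidy.elbow_curve <- function(x, ...) {
  tibble::tibble(k = x$k, score = x$score, scoring = x$scoring)
}

#' Detect the knee (elbow) of an elbow curve
#'
#' For distortion curves, a Kneedle-style rule: k and score are rescaled to
#' the unit square, the decreasing curve is flipped to an increasing one, and
#' the knee is the k maximising the difference between the flipped curve and
#' the diagonal. When that maximum difference falls below the sensitivity
#' threshold (`sensitivity` times the mean x-step, the Kneedle default of
#' S = 1), the curve has no discernible inflection and `NA` is returned —
#' flat or exactly linear curves have no elbow. For silhouette curves the
#' optimum is simply the k with the highest score. The rule is invariant to
#' positive rescaling of the scores.
#'
#' @param curve An [elbow_curve()].
#' @param sensitivity Kneedle sensitivity S (default 1).
#' @return The selected k, or `NA` when no elbow is discernible.
#' @export
detect_knee <- function(curve, sensitivity = 1) {
  stopifnot(inherits(curve, "elbow_curve"))
  k <- curve$k; y <- curve$score
  if (curve$scoring == "silhouette") {
    return(k[which.max(y)])
  }
  if (length(k) < 3) abort_validation("a distortion knee needs >= 3 points.")
  if (max(y) == min(y)) return(NA_integer_)     # flat curve: no elbow
  x_n <- (k - min(k)) / (max(k) - min(k))
  y_n <- (y - min(y)) / (max(y) - min(y))
  diff_curve <- (1 - y_n) - x_n
  threshold <- sensitivity * mean(diff(x_n))
  if (max(diff_curve) < threshold) return(NA_integer_)
  k[which.max(diff_curve)]
}
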