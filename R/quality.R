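#' Mean silhouette coefficient
#'
#' For each molecule i in cluster `C_I`, the mean intra-cluster distance
#' `a_i = mean(d(i, j)), j in C_I, j != i`, the mean distance to the nearest
#' other cluster `b_i = min_J mean(d(i, j)), j in C_J`, and the silhouette
#' `SC(i) = (b_i - a_i) / max(a_i, b_i)`. Molecules in singleton clusters
#' contribute `SC(i) = 0` (the usual convention; `a_i` is undefined there).
#' The score is the mean of `SC(i)` over all molecules: 1 is best, -1 worst,
#' values near 0 indicate overlapping clusters.
#'
#' @param x Either a numeric feature matrix (rows = molecules; Euclidean
#'   distances are used) or a precomputed `dist` object.
#' @param labels Integer cluster labels (`1..k`, no empty cluster).
#' @return A list of class `silhouette_result` with `score` (the mean) and
#'   `terms` (a per-molecule tibble with `cluster`, `a`, `b`, `sc`).
#' @export
silhouette_mean <- function(x, labels) {
  D <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(stats::dist(x))
  n <- nrow(D)
  labels <- check_labels(labels, n)
  k <- max(labels)
  if (k < 2) abort_validation("silhouette needs at least 2 clusters.")
  sizes <- tabulate(labels, k)

  # column-group sums of distances: n x k matrix of sum_{j in C_J} d(i, j)
  sums <- t(rowsum(t(D), labels))
  own_sum <- sums[cbind(seq_len(n), labels)]
  a <- unname(own_sum / (sizes[labels] - 1))    # NaN for singletons
  means_other <- sums / rep(sizes, each = n)
  means_other[cbind(seq_len(n), labels)] <- Inf
  b <- unname(apply(means_other, 1, min))
  sc <- (b - a) / pmax(a, b)
  sc[sizes[labels] == 1] <- 0                   # singleton convention
  structure(
    list(score = mean(sc),
         terms = tibble::tibble(cluster = labels, a = a, b = b, sc = sc)),
    class = "silhouette_result"
  )
}

#' @export
print.silhouette_result <- function(x, ...) {
  cat(sprintf("<silhouette_result> mean SC = %.4f over %d molecules\n",
              x$score, nrow(x$terms)))
  invisible(x)
}

#' Calinski-Harabasz score (variance ratio criterion)
#'
#' `CH = (tr(B_k) / tr(W_k)) * (n - k) / (k - 1)`, where `tr(W_k)` is the
#' total within-cluster dispersion (sum of squared Euclidean deviations of
#' each point from its cluster centre) and `tr(B_k)` the between-cluster
#' dispersion (size-weighted squared deviations of cluster centres from the
#' grand centre). Higher is better. When every cluster is a single repeated
#' point (`tr(W_k) = 0`) the score is reported as `Inf` with a warning.
#'
#' @param points Numeric feature matrix (rows = molecules). Binary
#'   fingerprint rows are cast to reals.
#' @param labels Integer cluster labels (`1..k`), with `k >= 2`.
#' @return A list of class `ch_result` with `score` and the decomposition
#'   (`tr_W`, `tr_B`, `k`, `n`).
#' @export
calinski_harabasz <- function(points, labels) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  labels <- check_labels(labels, n)
  k <- max(labels)
  if (k < 2) abort_validation("Calinski-Harabasz needs at least 2 clusters.")
  sizes <- tabulate(labels, k)
  centers <- rowsum(points, labels) / sizes
  grand <- colMeans(points)
  tr_W <- sum((points - centers[labels, , drop = FALSE])^2)
  tr_B <- sum(sizes * rowSums(sweep(centers, 2, grand)^2))
  score <- if (tr_W == 0) {
    rlang::warn("zero within-cluster dispersion; Calinski-Harabasz is Inf.")
    Inf
  } else {
    (tr_B / tr_W) * (n - k) / (k - 1)
  }
  structure(list(score = score, tr_W = tr_W, tr_B = tr_B, k = k, n = n),
            class = "ch_result")
}

#' @export
print.ch_result <- function(x, ...) {
  cat(sprintf("<ch_result> CH = %.4g (tr_W = %.4g, tr_B = %.4g, k = %d, n = %d)\n",
              x$score, x$tr_W, x$tr_B, x$k, x$n))
  invisible(x)
}

#' Davies-Bouldin score
#'
#' For each cluster, `s_i` is the mean Euclidean distance of its members to
#' the cluster centroid; for each pair, `R_ij = (s_i + s_j) / d_ij` with
#' `d_ij` the centroid distance. The score is the mean over clusters of the
#' worst ratio, `DB = (1/k) * sum_i max_{j != i} R_ij`. Zero is the best
#' possible value; lower is better. Coincident centroids with non-zero
#' scatter give an `Inf` sentinel.
#'
#' @inheritParams calinski_harabasz
#' @return A list of class `db_result` with `score`, per-cluster scatter `s`
#'   and the centroid-distance matrix `d_centroid`.
#' @export
davies_bouldin <- function(points, labels) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  labels <- check_labels(labels, n)
  k <- max(labels)
  if (k < 2) abort_validation("Davies-Bouldin needs at least 2 clusters.")
  sizes <- tabulate(labels, k)
  centers <- rowsum(points, labels) / sizes
  dev <- points - centers[labels, , drop = FALSE]
  s <- as.numeric(rowsum(sqrt(rowSums(dev^2)), labels)) / sizes
  d_centroid <- as.matrix(stats::dist(centers))
  R <- outer(s, s, `+`) / d_centroid            # Inf/NaN on the diagonal
  R[d_centroid == 0 & outer(s, s, `+`) == 0] <- 0
  diag(R) <- -Inf
  score <- mean(apply(R, 1, max))
  structure(list(score = score, s = s, d_centroid = d_centroid),
            class = "db_result")
}

#' @export
print.db_result <- function(x, ...) {
  cat(sprintf("<db_result> DB = %.4g over %d clusters\n",
              x$score, length(x$s)))
  invisible(x)
}

check_labels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n) abort_validation("one label per molecule required.")
  k <- max(labels)
  if (min(labels) != 1L || !setequal(unique(labels), seq_len(k))) {
    abort_validation("labels must cover 1..k with no empty cluster.")
  }
  labels
}

#' Average inter/intra-cluster Tanimoto similarity matrix
#'
#' Entry `(p, q)` is the mean Tanimoto similarity between the molecules of
#' cluster p and those of cluster q. Diagonal entries average over unordered
#' pairs of *distinct* molecules within the cluster (self-similarities are
#' excluded), and are therefore missing (`NA`) for singleton clusters. The
#' matrix is symmetric; in a well-separated clustering every defined diagonal
#' entry exceeds the off-diagonal entries in its row.
#'
#' @param fps A [fingerprint_set()].
#' @param labels Integer cluster labels or a [cluster_assignment()] (must be
#'   in the same molecule order as `fps`).
#' @param block_size Row-block size for the pairwise pass.
#' @return An object of class `avg_sim_matrix`: a list with `matrix` (k x k),
#'   `sizes` and `method`.
#' @export
average_similarity_matrix <- function(fps, labels, block_size = 256L) {
  stopifnot(is_fingerprint_set(fps))
  method <- NULL
  if (inherits(labels, "cluster_assignment")) {
    if (!identical(labels$ids, fps$ids)) {
      abort_validation("assignment ids do not match the fingerprint set.")
    }
    method <- labels$method
    labels <- labels$labels
  }
  n <- nrow(fps$bits)
  labels <- check_labels(labels, n)
  k <- max(labels)
  sizes <- tabulate(labels, k)

  X <- fps$bits
  storage.mode(X) <- "double"
  row_on <- rowSums(X)
  total <- matrix(0, k, k)     # ordered-pair similarity sums incl. self
  self_sum <- numeric(k)
  fct <- factor(labels, levels = seq_len(k))
  for (start in seq(1, n, by = block_size)) {
    rows <- start:min(start + block_size - 1, n)
    sim <- block_similarity(X[rows, , drop = FALSE], X, row_on[rows], row_on)
    by_col <- t(rowsum(t(sim), fct))                 # m x k
    part <- rowsum(by_col, fct[rows])                # clusters-in-block x k
    idx <- as.integer(rownames(part))
    total[idx, ] <- total[idx, ] + part
    selfs <- sim[cbind(seq_along(rows), rows)]
    self_sum <- self_sum + as.numeric(
      tapply(selfs, fct[rows], sum, default = 0))
  }
  mat <- total / outer(sizes, sizes)
  diag(mat) <- ifelse(sizes > 1,
                      (diag(total) - self_sum) / (sizes * (sizes - 1)),
                      NA_real_)
  structure(list(matrix = mat, sizes = sizes, method = method),
            class = "avg_sim_matrix")
}

#' @export
print.avg_sim_matrix <- function(x, digits = 3, ...) {
  k <- nrow(x$matrix)
  cat(sprintf("<avg_sim_matrix> %d clusters (sizes %s)\n", k,
              paste(x$sizes, collapse = ", ")))
  m <- round(x$matrix, digits)
  m[upper.tri(m)] <- NA                       # display as lower triangle
  print(m, na.print = "")
  invisible(x)
}

#' Tidy an average similarity matrix into long form
#'
#' @param x An `avg_sim_matrix`.
#' @param ... Unused.
#' @return A tibble with `cluster_i`, `cluster_j`, `mean_similarity` and
#'   `within` (logical diagonal flag), one row per unordered cluster pair.
#' @export
tidy.avg_sim_matrix <- function(x, ...) {
  k <- nrow(x$matrix)
  idx <- which(lower.tri(x$matrix, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    cluster_i = idx[, "row"], cluster_j = idx[, "col"],
    mean_similarity = x$matrix[idx],
    within = idx[, "row"] == idx[, "col"]
  )
}

#' Write an average similarity matrix as CSV
#'
#' Missing diagonal entries (singleton clusters) are left empty.
#'
#' @param x An `avg_sim_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_avg_sim_matrix <- function(x, path) {
  m <- as.data.frame(x$matrix)
  names(m) <- paste0("cluster", seq_len(ncol(m)))
  readr::write_csv(m, path, na = "")
  invisible(path)
}

#' Descriptive statistics of cluster sizes
#'
#' Mean, sample standard deviation, minimum, the 10/17/20/25/50/75 percentiles
#' (linear interpolation between order statistics) and maximum of the cluster
#' sizes.
#'
#' @param labels Integer cluster labels or a [cluster_assignment()].
#' @return A one-row tibble.
#' @export
cluster_size_summary <- function(labels) {
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  sizes <- tabulate(check_labels(labels, length(labels)))
  q <- stats::quantile(sizes, c(.10, .17, .20, .25, .50, .75), type = 7)
  tibble::tibble(
    n_clusters = length(sizes), mean = mean(sizes),
    std = if (length(sizes) > 1) stats::sd(sizes) else 0,
    min = min(sizes),
    p10 = q[[1]], p17 = q[[2]], p20 = q[[3]], p25 = q[[4]],
    p50 = q[[5]], p75 = q[[6]], max = max(sizes)
  )
}

#' Score one clustering with the three validity indices
#'
#' Computes the mean silhouette, Calinski-Harabasz and Davies-Bouldin scores
#' of a cluster assignment in a chosen feature space, plus the cluster count.
#' For fingerprint-space clusterings (Ward, Taylor-Butina) the indices are
#' computed on the binary fingerprint matrix under Euclidean geometry; for
#' embedding-based clusterings pass the embedding coordinates instead.
#' Degenerate clusterings (fewer than 2 clusters, or k = n for CH) yield `NA`
#' for the affected metrics rather than fabricated values.
#'
#' @param x Feature space: a [fingerprint_set()] or a numeric matrix.
#' @param cl A [cluster_assignment()] (or integer labels) in the same
#'   molecule order.
#' @return A one-row tibble: `method`, `n_molecules`, `n_clusters`,
#'   `silhouette`, `calinski_harabasz`, `davies_bouldin`.
#' @export
quality_report <- function(x, cl) {
  points <- if (is_fingerprint_set(x)) x$bits else as.matrix(x)
  storage.mode(points) <- "double"
  method <- NA_character_
  labels <- cl
  if (inherits(cl, "cluster_assignment")) {
    method <- cl$method
    labels <- cl$labels
  }
  n <- nrow(points)
  labels <- check_labels(labels, n)
  k <- max(labels)
  sil <- ch <- db <- NA_real_
  if (k >= 2) {
    sil <- silhouette_mean(points, labels)$score
    db <- davies_bouldin(points, labels)$score
    if (k < n) ch <- calinski_harabasz(points, labels)$score
  }
  tibble::tibble(method = method, n_molecules = n, n_clusters = k,
                 silhouette = sil, calinski_harabasz = ch,
                 davies_bouldin = db)
}
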