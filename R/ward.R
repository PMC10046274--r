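#' Ward agglomerative clustering from a precomputed distance matrix
#'
#' Builds the binary merge tree by greedy agglomeration under the Ward
#' criterion, implemented directly from the Lance-Williams recurrence on
#' squared distances: after merging clusters i and j, the squared distance of
#' the union to any third cluster k is
#' `d(ij,k)^2 = ((n_i + n_k) d(i,k)^2 + (n_j + n_k) d(j,k)^2 - n_k d(i,j)^2) /
#' (n_i + n_j + n_k)`.
#' Two singletons merge at their input distance, so merge heights live on the
#' scale of the supplied distances (for Tanimoto distances, heights of a few
#' units are typical at the top of the tree). Ties in the minimum-distance
#' search are broken deterministically towards the lowest pair index.
#'
#' @param d A `dist` object (e.g. from [tanimoto_distance()]) over at least 2
#'   items.
#' @return An object of class `linkage_tree`: a list with `merges` (tibble
#'   with columns `left`, `right`, `height`, `size`; negative entries denote
#'   leaves, positive entries earlier merges, as in [stats::hclust]),
#'   `n_leaves` and `labels`.
#' @export
ward_linkage <- function(d) {
  if (!inherits(d, "dist")) abort_validation("`d` must be a `dist` object.")
  n <- attr(d, "Size")
  if (is.null(n) || n < 2) abort_validation("need at least 2 items to cluster.")
  labels <- attr(d, "Labels") %||% as.character(seq_len(n))

  D2 <- as.matrix(d)^2
  diag(D2) <- Inf
  sizes <- rep(1, n)
  node <- -seq_len(n)                  # hclust convention: leaves negative
  active <- rep(TRUE, n)

  left <- integer(n - 1); right <- integer(n - 1)
  height <- numeric(n - 1); msize <- integer(n - 1)

  for (m in seq_len(n - 1)) {
    flat <- which.min(D2)              # first minimum in column-major order
    j <- (flat - 1) %/% n + 1
    i <- flat - (j - 1) * n
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    h2 <- D2[i, j]
    height[m] <- sqrt(h2)
    pair <- sort(c(node[i], node[j]))
    left[m] <- pair[1]; right[m] <- pair[2]
    msize[m] <- sizes[i] + sizes[j]

    k <- which(active); k <- k[k != i & k != j]
    if (length(k) > 0) {
      newd <- ((sizes[i] + sizes[k]) * D2[i, k] +
               (sizes[j] + sizes[k]) * D2[j, k] -
               sizes[k] * h2) / (sizes[i] + sizes[j] + sizes[k])
      D2[i, k] <- newd
      D2[k, i] <- newd
    }
    sizes[i] <- sizes[i] + sizes[j]
    node[i] <- m
    active[j] <- FALSE
    D2[j, ] <- Inf
    D2[, j] <- Inf
  }

  structure(
    list(merges = tibble::tibble(left = left, right = right,
                                 height = height, size = msize),
         n_leaves = n, labels = labels),
    class = "linkage_tree"
  )
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %d leaves, %d merges, root height %.4g\n",
              x$n_leaves, nrow(x$merges), max(x$merges$height)))
  invisible(x)
}

#' @export
tidy.linkage_tree <- function(x, ...) x$merges

#' Convert a linkage tree to a base-R hclust object
#'
#' @param x A `linkage_tree` from [ward_linkage()].
#' @param ... Unused.
#' @return A [stats::hclust] object (usable with `plot()`, `cutree()`, ...).
#' @export
as.hclust.linkage_tree <- function(x, ...) {
  n <- x$n_leaves
  merge <- cbind(x$merges$left, x$merges$right)
  # leaf order via iterative tree traversal (left-to-right)
  order <- integer(0)
  stack <- nrow(merge)
  while (length(stack) > 0) {
    top <- stack[[1]]; stack <- stack[-1]
    if (top < 0) order <- c(order, -top)
    else stack <- c(merge[top, 1], merge[top, 2], stack)
  }
  structure(list(merge = merge, height = x$merges$height, order = order,
                 labels = x$labels, method = "ward",
                 call = match.call(), dist.method = "precomputed"),
            class = "hclust")
}

#' Write a linkage tree as a plain-text merge table
#'
#' Four tab-separated columns per merge: `left`, `right`, `height`, `size`.
#'
#' @param tree A `linkage_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_linkage_tree <- function(tree, path) {
  readr::write_tsv(tree$merges, path)
  invisible(path)
}

#' Cut a linkage tree into flat clusters
#'
#' Either at a linkage-height cutoff (cophenetic criterion: all merges with
#' height `<= height_cutoff` are applied, so stricter/smaller cutoffs give
#' more clusters) or into exactly `k` clusters (the last `k - 1` merges are
#' left unapplied). Cluster labels are assigned in order of first leaf
#' appearance.
#'
#' @param tree A `linkage_tree` from [ward_linkage()].
#' @param height_cutoff Positive linkage-height cutoff.
#' @param k Exact number of clusters (alternative to `height_cutoff`).
#' @param method Method tag recorded on the result (default `"ward"`).
#' @return A [cluster_assignment()].
#' @export
cut_tree <- function(tree, height_cutoff = NULL, k = NULL, method = "ward") {
  stopifnot(inherits(tree, "linkage_tree"))
  n <- tree$n_leaves
  if (is.null(height_cutoff) == is.null(k)) {
    abort_validation("supply exactly one of `height_cutoff` or `k`.")
  }
  if (!is.null(height_cutoff)) {
    if (height_cutoff <= 0) abort_validation("`height_cutoff` must be positive.")
    apply_m <- which(tree$merges$height <= height_cutoff)
    params <- list(height_cutoff = height_cutoff)
  } else {
    if (k < 1 || k > n) abort_validation("`k` must lie in [1, n].")
    apply_m <- seq_len(n - k)
    params <- list(k = k)
  }

  parent <- seq_len(n)                 # union-find over leaves
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # leaf representative of each merge node, for unions between internal nodes
  rep_leaf <- integer(nrow(tree$merges))
  leaf_of <- function(node) if (node < 0) -node else rep_leaf[node]
  apply_mask <- rep(FALSE, nrow(tree$merges))
  apply_mask[apply_m] <- TRUE
  for (m in seq_len(nrow(tree$merges))) {
    l <- leaf_of(tree$merges$left[m]); r <- leaf_of(tree$merges$right[m])
    rep_leaf[m] <- l
    if (apply_mask[m]) {
      rl <- find(l); rr <- find(r)
      if (rl != rr) parent[rr] <- rl
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))  # first-appearance numbering
  cluster_assignment(tree$labels, labels, method = method, params = params)
}
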