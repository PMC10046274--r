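#' Construct a cluster assignment
#'
#' The common result type of all three clustering routes: per-molecule integer
#' cluster labels (`1..k`, numbered in order of first appearance, no empty
#' cluster) plus method metadata. Taylor-Butina assignments additionally carry
#' a per-molecule role (`centroid`, `member` or `singleton`).
#'
#' @param ids Molecule identifiers.
#' @param labels Integer cluster labels, one per molecule.
#' @param method One of `"ward"`, `"butina"`, `"umap_agglomerative"`.
#' @param params Named list of the parameters that produced the clustering.
#' @param butina_role Optional character vector of per-molecule roles
#'   (Taylor-Butina only).
#' @return An object of class `cluster_assignment`.
#' @export
cluster_assignment <- function(ids, labels, method, params = list(),
                               butina_role = NULL) {
  labels <- as.integer(labels)
  if (length(ids) != length(labels)) {
    abort_validation("`ids` and `labels` must have the same length.")
  }
  k <- max(labels)
  if (length(labels) > 0 &&
      (min(labels) != 1L || !setequal(unique(labels), seq_len(k)))) {
    abort_validation("labels must cover 1..k with no empty cluster.")
  }
  if (!is.null(butina_role) && method != "butina") {
    abort_validation("`butina_role` is only meaningful for method = \"butina\".")
  }
  structure(
    list(ids = as.character(ids), labels = labels, method = method,
         params = params, butina_role = butina_role),
    class = "cluster_assignment"
  )
}

n_clusters <- function(cl) if (length(cl$labels) == 0) 0L else max(cl$labels)

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- tabulate(x$labels)
  cat(sprintf("<cluster_assignment> %s: %d molecules in %d clusters\n",
              x$method, length(x$labels), n_clusters(x)))
  if (length(x$params) > 0) {
    cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                           collapse = ", "), "\n")
  }
  if (!is.null(x$butina_role)) {
    cat(sprintf("  singletons: %d\n", sum(x$butina_role == "singleton")))
  } else if (length(sizes) > 0) {
    cat(sprintf("  largest cluster: %d molecules\n", max(sizes)))
  }
  invisible(x)
}

#' Tidy a cluster assignment into one row per molecule
#'
#' @param x A [cluster_assignment()].
#' @param ... Unused.
#' @return A tibble with columns `id`, `cluster` and, for Taylor-Butina
#'   results, `role`.
#' @export
tidy.cluster_assignment <- function(x, ...) {
  out <- tibble::tibble(id = x$ids, cluster = x$labels)
  if (!is.null(x$butina_role)) out$role <- x$butina_role
  out
}

#' One-row summary of a cluster assignment
#'
#' @param x A [cluster_assignment()].
#' @param ... Unused.
#' @return A tibble with `method`, `n_molecules`, `n_clusters`,
#'   `n_singletons` and `largest_cluster`.
#' @export
glance.cluster_assignment <- function(x, ...) {
  sizes <- tabulate(x$labels)
  tibble::tibble(
    method = x$method,
    n_molecules = length(x$labels),
    n_clusters = n_clusters(x),
    n_singletons = sum(sizes == 1L),
    largest_cluster = if (length(sizes) > 0) max(sizes) else 0L
  )
}

#' Write a cluster assignment as TSV
#'
#' One row per molecule: `id`, `cluster`, and `role` for Taylor-Butina.
#'
#' @param cl A [cluster_assignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cluster_assignment <- function(cl, path) {
  readr::write_tsv(tidy(cl), path)
  invisible(path)
}
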