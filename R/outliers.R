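#' Flag outlier molecules by nearest-neighbour similarity
#'
#' A molecule is an outlier when the Tanimoto similarity to its most similar
#' molecule in the set is lower than or equal to the cutoff: at that
#' similarity level it is different from every other molecule in the library.
#' The rule is applied in a single pass over the full-set nearest-neighbour
#' profile; similarities are not recomputed after removals.
#'
#' @param profile A nearest-neighbour profile tibble from
#'   [nearest_neighbor_profile()] (columns `id`, `nn_sim`).
#' @param cutoff Similarity cutoff in `[0, 1]`; molecules with
#'   `nn_sim <= cutoff` are flagged.
#' @return An object of class `outlier_report`: a list with `cutoff`,
#'   `outlier_ids`, `retained_ids` and `n_removed`.
#' @export
flag_outliers <- function(profile, cutoff) {
  stopifnot(is.data.frame(profile), all(c("id", "nn_sim") %in% names(profile)))
  if (nrow(profile) == 0) abort_validation("empty nearest-neighbour profile.")
  if (cutoff < 0 || cutoff > 1) abort_validation("`cutoff` must lie in [0, 1].")
  is_out <- profile$nn_sim <= cutoff
  structure(
    list(cutoff = cutoff,
         outlier_ids = profile$id[is_out],
         retained_ids = profile$id[!is_out],
         n_removed = sum(is_out)),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  n <- length(x$outlier_ids) + length(x$retained_ids)
  cat(sprintf("<outlier_report> cutoff %.3g: %d of %d molecules flagged (%.1f%%)\n",
              x$cutoff, x$n_removed, n, 100 * x$n_removed / n))
  invisible(x)
}

#' Tidy an outlier report into one row per molecule
#'
#' @param x An `outlier_report` from [flag_outliers()].
#' @param ... Unused.
#' @return A tibble with columns `id` and `is_outlier`.
#' @export
tidy.outlier_report <- function(x, ...) {
  tibble::tibble(
    id = c(x$retained_ids, x$outlier_ids),
    is_outlier = rep(c(FALSE, TRUE),
                     c(length(x$retained_ids), length(x$outlier_ids)))
  )
}

#' Scan outlier cutoffs against a baseline clustering
#'
#' For each candidate cutoff: flag and remove outliers on the full-set
#' nearest-neighbour profile, re-cluster the retained molecules with Ward
#' agglomeration on Tanimoto distances cut at a fixed linkage height, and
#' score the result with the three validity indices (computed on the binary
#' fingerprint matrix under Euclidean geometry). Cutoffs that leave fewer
#' than two molecules, or a single cluster, yield `NA` metrics rather than
#' fabricated numbers.
#'
#' @param fps A [fingerprint_set()].
#' @param cutoffs Ascending vector of similarity cutoffs.
#' @param ward_cutoff Linkage-height cutoff of the baseline Ward clustering
#'   (default 3).
#' @param block_size Block size for the pairwise computations.
#' @return A tibble with one row per cutoff: `cutoff`, `n_removed`,
#'   `n_clusters`, `silhouette`, `calinski_harabasz`, `davies_bouldin`.
#' @export
scan_outlier_cutoffs <- function(fps, cutoffs, ward_cutoff = 3,
                                 block_size = 256L) {
  stopifnot(is_fingerprint_set(fps))
  if (length(cutoffs) == 0) {
    return(tibble::tibble(cutoff = numeric(0), n_removed = integer(0),
                          n_clusters = integer(0), silhouette = numeric(0),
                          calinski_harabasz = numeric(0),
                          davies_bouldin = numeric(0)))
  }
  if (is.unsorted(cutoffs)) abort_validation("`cutoffs` must be ascending.")
  profile <- nearest_neighbor_profile(fps, block_size = block_size)
  purrr::map_dfr(cutoffs, function(co) {
    rep <- flag_outliers(profile, co)
    na_row <- tibble::tibble(cutoff = co, n_removed = rep$n_removed,
                             n_clusters = NA_integer_, silhouette = NA_real_,
                             calinski_harabasz = NA_real_,
                             davies_bouldin = NA_real_)
    if (length(rep$retained_ids) < 2) return(na_row)
    kept <- fps[rep$retained_ids]
    cl <- cut_tree(ward_linkage(tanimoto_distance(kept, block_size = block_size)),
                   height_cutoff = ward_cutoff)
    q <- quality_report(kept, cl)
    tibble::tibble(cutoff = co, n_removed = rep$n_removed,
                   n_clusters = q$n_clusters, silhouette = q$silhouette,
                   calinski_harabasz = q$calinski_harabasz,
                   davies_bouldin = q$davies_bouldin)
  })
}

#' Histogram-gap similarity cutoff
#'
#' Chooses an outlier cutoff from a bimodal nearest-neighbour similarity
#' distribution: the midpoint of the widest gap between consecutive sorted
#' `nn_sim` values (restricted to an optional search window). With planted
#' random-fingerprint outliers the low-similarity mode separates cleanly from
#' the cluster-member mode, and the widest gap falls between them.
#'
#' @param nn_sim Numeric vector of nearest-neighbour similarities.
#' @param window Length-2 numeric: only gaps whose midpoint lies inside this
#'   similarity window are considered (default the full `[0, 1]` range).
#' @return A single cutoff value.
#' @export
gap_cutoff <- function(nn_sim, window = c(0, 1)) {
  s <- sort(unique(nn_sim))
  if (length(s) < 2) abort_validation("need at least two distinct nn_sim values.")
  mids <- (s[-length(s)] + s[-1]) / 2
  gaps <- diff(s)
  ok <- mids >= window[1] & mids <= window[2]
  if (!any(ok)) abort_validation("no similarity gap inside the window.")
  mids[ok][which.max(gaps[ok])]
}
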