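#' Number of unordered molecule pairs
#'
#' The length of a condensed pairwise distance vector for `n` molecules,
#' i.e. `n * (n - 1) / 2`. Computed in double precision so that library-scale
#' counts (billions of pairs) are exact, since they stay far below 2^53.
#'
#' @param n Number of molecules (non-negative integer).
#' @return A double: the number of unordered pairs.
#' @examples
#' pair_count(4)     # 6
#' pair_count(50555) # 1277878735
#' @export
pair_count <- function(n) {
  stopifnot(is.numeric(n), length(n) >= 1, all(n >= 0), all(n == floor(n)))
  n * (n - 1) / 2
}

#' Percentage share of a subset
#'
#' @param part,whole Counts with `0 <= part <= whole`, `whole > 0`.
#' @return `100 * part / whole`.
#' @examples
#' percent_share(17691, 50555)
#' @export
percent_share <- function(part, whole) {
  stopifnot(is.numeric(part), is.numeric(whole), all(whole > 0))
  100 * part / whole
}

#' Relative improvement between two scores
#'
#' Percentage change from a reference score to a new score, oriented so that a
#' positive value always means "better". For scores where larger is better
#' (silhouette, Calinski-Harabasz) this is `100 * (new - ref) / |ref|`; for
#' scores where smaller is better (Davies-Bouldin) the sign is flipped.
#'
#' @param ref Reference score.
#' @param new New score.
#' @param larger_is_better Orientation of the score (default `TRUE`).
#' @return Percentage improvement (positive = improvement).
#' @examples
#' relative_improvement(-0.014, -0.007)                       # silhouette: +50
#' relative_improvement(77.19, 67.15, larger_is_better = FALSE) # DB: +13
#' @export
relative_improvement <- function(ref, new, larger_is_better = TRUE) {
  stopifnot(is.numeric(ref), is.numeric(new))
  delta <- if (larger_is_better) new - ref else ref - new
  100 * delta / abs(ref)
}

# Condensed (lower-triangle, column-major) index of pair (i, j), i < j,
# 1-based, matching the storage order of stats::dist.
condensed_index <- function(i, j, n) {
  stopifnot(all(i < j), all(j <= n))
  n * (i - 1) - i * (i - 1) / 2 + (j - i)
}

# Internal abort helpers keep error classes consistent across the package.
mc_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "molclust_error"))
}
abort_validation <- function(msg) mc_abort(msg, "molclust_validation_error")
abort_format     <- function(msg) mc_abort(msg, "molclust_format_error")
abort_environment <- function(msg) mc_abort(msg, "molclust_environment_error")
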