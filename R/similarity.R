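#' Tanimoto similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`, the standard similarity coefficient for binary
#' substructure fingerprints (1 minus the Jaccard distance). Two all-zero
#' fingerprints are defined to have similarity 0: an empty fingerprint shares
#' no substructure with anything, itself included.
#'
#' @param a,b Binary 0/1 vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 0), c(1, 0, 1)) # 1/3
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) abort_validation("fingerprints differ in length.")
  inter <- sum(a == 1L & b == 1L)
  union <- sum(a == 1L | b == 1L)
  if (union == 0) return(0)
  inter / union
}

# Tanimoto similarities between rows of block B (m x L) and rows of X (n x L).
# Dense double crossprod: one m x n block in memory at a time.
block_similarity <- function(B, X, row_on_B, row_on_X) {
  inter <- tcrossprod(B, X)                       # m x n intersection counts
  union <- outer(row_on_B, row_on_X, `+`) - inter
  sim <- inter / union
  sim[union == 0] <- 0                            # all-zero vs all-zero pairs
  sim
}

#' Pairwise Tanimoto distance matrix
#'
#' Computes `1 - Tanimoto` for every unordered pair of molecules and returns
#' the condensed (lower-triangle) distance vector as a [stats::dist] object.
#' The computation proceeds in row blocks so that, apart from the condensed
#' result itself, peak memory is `O(block_size * n)` regardless of library
#' size.
#'
#' @param fps A [fingerprint_set()] with at least 2 molecules.
#' @param block_size Number of molecules per block (default 256).
#' @return A `dist` object of length `n(n-1)/2`, with `Labels` set to the
#'   molecule ids and `method = "tanimoto"`.
#' @export
tanimoto_distance <- function(fps, block_size = 256L) {
  stopifnot(is_fingerprint_set(fps))
  n <- nrow(fps$bits)
  if (n < 2) abort_validation("need at least 2 molecules for pairwise distances.")
  X <- fps$bits
  storage.mode(X) <- "double"
  row_on <- rowSums(X)
  values <- numeric(pair_count(n))
  for (start in seq(1, n - 1, by = block_size)) {
    end <- min(start + block_size - 1, n - 1)
    rows <- start:end
    # pairs (i, j) with i in rows, j > i
    sim <- block_similarity(X[rows, , drop = FALSE], X, row_on[rows], row_on)
    for (k in seq_along(rows)) {
      i <- rows[k]
      j <- (i + 1):n
      values[condensed_index(i, j, n)] <- 1 - sim[k, j]
    }
  }
  structure(values, class = "dist", Size = n, Labels = fps$ids,
            Diag = FALSE, Upper = FALSE, method = "tanimoto",
            call = match.call())
}

#' Nearest-neighbour Tanimoto similarity profile
#'
#' For every molecule, the maximum Tanimoto similarity to any *other* molecule
#' in the set, together with the identity of that closest molecule. Computed
#' in streaming row blocks, so the full pairwise matrix is never materialised:
#' only the `n` retained maxima are kept, which is what makes the profile
#' usable on libraries where the pair count runs into the billions. Ties are
#' broken towards the lowest molecule index.
#'
#' @param fps A [fingerprint_set()] with at least 2 molecules.
#' @param block_size Number of molecules per block (default 256).
#' @return A tibble with columns `id`, `nn_id`, `nn_sim`, in input order.
#' @export
nearest_neighbor_profile <- function(fps, block_size = 256L) {
  stopifnot(is_fingerprint_set(fps))
  n <- nrow(fps$bits)
  if (n < 2) abort_validation("a nearest neighbour needs at least 2 molecules.")
  X <- fps$bits
  storage.mode(X) <- "double"
  row_on <- rowSums(X)
  nn_sim <- numeric(n)
  nn_idx <- integer(n)
  for (start in seq(1, n, by = block_size)) {
    end <- min(start + block_size - 1, n)
    rows <- start:end
    sim <- block_similarity(X[rows, , drop = FALSE], X, row_on[rows], row_on)
    sim[cbind(seq_along(rows), rows)] <- -Inf   # exclude self
    best <- max.col(sim, ties.method = "first")
    nn_idx[rows] <- best
    nn_sim[rows] <- sim[cbind(seq_along(rows), best)]
  }
  tibble::tibble(id = fps$ids, nn_id = fps$ids[nn_idx], nn_sim = nn_sim)
}
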