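#' Taylor-Butina exclusion-sphere clustering
#'
#' Single-pass sphere-exclusion clustering at a fixed Tanimoto level. Molecule
#' j is a neighbour of molecule i when `tanimoto(i, j) >= similarity_cutoff`.
#' At each iteration the unassigned molecule with the most *unassigned*
#' neighbours becomes the centroid of a new cluster and absorbs all of its
#' unassigned neighbours; every member therefore lies within the centroid's
#' exclusion sphere. Molecules left without a cluster at the end are
#' singletons — possibly "false singletons" whose only neighbours were
#' attracted by a better centroid. Ties in the neighbour count are broken
#' towards the lowest molecule index.
#'
#' @param d A `dist` object of Tanimoto distances (`1 - similarity`), e.g.
#'   from [tanimoto_distance()].
#' @param similarity_cutoff Tanimoto similarity cutoff in `(0, 1]`.
#' @return A [cluster_assignment()] with `method = "butina"` and per-molecule
#'   roles (`centroid`, `member`, `singleton`). Clusters are renumbered in
#'   order of first molecule appearance; singletons count as clusters.
#' @export
butina_cluster <- function(d, similarity_cutoff) {
  if (!inherits(d, "dist")) abort_validation("`d` must be a `dist` object.")
  if (similarity_cutoff <= 0 || similarity_cutoff > 1) {
    abort_validation("`similarity_cutoff` must lie in (0, 1].")
  }
  n <- attr(d, "Size")
  ids <- attr(d, "Labels") %||% as.character(seq_len(n))
  S <- 1 - as.matrix(d)
  diag(S) <- 0
  adj <- S >= similarity_cutoff        # neighbour graph (excludes self)

  labels <- integer(n)
  role <- character(n)
  unassigned <- rep(TRUE, n)
  next_cluster <- 0L
  repeat {
    counts <- rowSums(adj[, unassigned, drop = FALSE]) # unassigned neighbours
    counts[!unassigned] <- -1
    best <- which.max(counts)          # ties -> lowest index
    if (counts[best] <= 0) break       # no molecule has unassigned neighbours
    members <- which(adj[best, ] & unassigned)
    next_cluster <- next_cluster + 1L
    labels[c(best, members)] <- next_cluster
    role[best] <- "centroid"
    role[members] <- "member"
    unassigned[c(best, members)] <- FALSE
  }
  for (i in which(unassigned)) {
    next_cluster <- next_cluster + 1L
    labels[i] <- next_cluster
    role[i] <- "singleton"
  }
  # relabel in order of first appearance to keep the label invariant uniform
  labels <- match(labels, unique(labels))
  cluster_assignment(ids, labels, method = "butina",
                     params = list(similarity_cutoff = similarity_cutoff),
                     butina_role = role)
}
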