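#' Embed fingerprints in a low-dimensional space with UMAP
#'
#' Delegates manifold embedding to the external `umap-learn` implementation
#' (driven through the system `python`); the embedding optimiser itself is
#' deliberately not re-implemented here. Fingerprint rows are compared with
#' the Jaccard metric (`1 - Tanimoto`), and the random state is always seeded
#' so that identical inputs give identical embeddings on a fixed environment.
#'
#' @param fps A [fingerprint_set()].
#' @param n_neighbors Local/global balance of the embedding (>= 2, and < n).
#' @param min_dist Minimum distance between embedded points, in `[0, 1)`.
#' @param n_components Embedding dimensionality (default 2).
#' @param metric Ambient-space metric (default `"jaccard"`).
#' @param seed Random state of the embedding optimiser (default 42).
#' @return An `n x n_components` numeric matrix with molecule ids as row
#'   names.
#' @export
umap_embed <- function(fps, n_neighbors = 15L, min_dist = 0.1,
                       n_components = 2L, metric = "jaccard", seed = 42L) {
  cfg <- tibble::tibble(n_neighbors = n_neighbors, min_dist = min_dist,
                        n_components = n_components, metric = metric,
                        seed = seed)
  umap_embed_batch(fps, cfg)[[1]]
}

# Run several UMAP embeddings of the same fingerprint set in one python
# process (the interpreter + JIT start-up dominates small embeddings).
# `configs` is a data frame with columns n_neighbors, min_dist, n_components,
# metric, seed; returns a list of embedding matrices, one per row.
umap_embed_batch <- function(fps, configs) {
  stopifnot(is_fingerprint_set(fps), is.data.frame(configs))
  n <- nrow(fps$bits)
  if (any(configs$n_neighbors < 2)) {
    abort_validation("`n_neighbors` must be at least 2.")
  }
  if (any(configs$n_neighbors >= n)) {
    abort_validation("`n_neighbors` must be smaller than the molecule count.")
  }
  if (any(configs$min_dist < 0 | configs$min_dist >= 1)) {
    abort_validation("`min_dist` must lie in [0, 1).")
  }
  if (any(configs$n_components < 1)) {
    abort_validation("`n_components` must be at least 1.")
  }

  bits_file <- tempfile(fileext = ".hex")
  cfg_file <- tempfile(fileext = ".tsv")
  out_dir <- tempfile("umap_out")
  dir.create(out_dir)
  on.exit(unlink(c(bits_file, cfg_file, out_dir), recursive = TRUE))

  writeLines(vapply(seq_len(n), function(i) bits_to_hex(fps$bits[i, ]),
                    character(1)), bits_file)
  readr::write_tsv(configs[, c("n_neighbors", "min_dist", "n_components",
                               "metric", "seed")], cfg_file, col_names = FALSE)

  code <- c(
    "import sys, os, warnings",
    "import numpy as np",
    "warnings.filterwarnings('ignore')",
    "try:",
    "    import umap",
    "except ImportError:",
    "    sys.exit(3)",
    "bits_file, n_bits, cfg_file, out_dir = sys.argv[1:5]",
    "n_bits = int(n_bits)",
    "rows = [bytes.fromhex(l.strip()) for l in open(bits_file)]",
    "X = np.unpackbits(np.frombuffer(b''.join(rows), dtype=np.uint8)",
    "                  .reshape(len(rows), -1), axis=1, bitorder='little')",
    "X = X[:, :n_bits].astype(np.float32)",
    "for i, line in enumerate(open(cfg_file)):",
    "    nn, md, nc, metric, seed = line.split('\\t')",
    "    emb = umap.UMAP(n_neighbors=int(nn), min_dist=float(md),",
    "                    n_components=int(nc), metric=metric,",
    "                    random_state=int(seed)).fit_transform(X)",
    "    np.savetxt(os.path.join(out_dir, f'{i}.csv'), emb, delimiter=',')"
  )
  run_python(code, c(bits_file, fps$n_bits, cfg_file, out_dir))

  lapply(seq_len(nrow(configs)) - 1L, function(i) {
    f <- file.path(out_dir, paste0(i, ".csv"))
    if (!file.exists(f)) abort_environment("embedding output missing.")
    emb <- as.matrix(utils::read.csv(f, header = FALSE))
    dimnames(emb) <- list(fps$ids, NULL)
    emb
  })
}

#' Ward agglomerative clustering of an embedding
#'
#' Agglomerates the rows of a low-dimensional embedding under the Ward
#' criterion on Euclidean distances (reusing [ward_linkage()]) and cuts the
#' tree into exactly `n_clusters` groups by leaving the last
#' `n_clusters - 1` merges unapplied.
#'
#' @param embedding Numeric matrix (rows = molecules), e.g. from
#'   [umap_embed()].
#' @param n_clusters Number of clusters to request (`<= n`).
#' @return A [cluster_assignment()] with `method = "umap_agglomerative"`.
#' @export
agglomerative_on_embedding <- function(embedding, n_clusters) {
  stopifnot(is.matrix(embedding))
  if (n_clusters < 1 || n_clusters > nrow(embedding)) {
    abort_validation("`n_clusters` must lie in [1, n].")
  }
  tree <- ward_linkage(stats::dist(embedding))
  cl <- cut_tree(tree, k = n_clusters, method = "umap_agglomerative")
  cl$params$n_clusters <- n_clusters
  cl
}

#' Embed and cluster in one step
#'
#' Convenience wrapper: [umap_embed()] followed by
#' [agglomerative_on_embedding()].
#'
#' @inheritParams umap_embed
#' @param n_clusters Number of clusters to request.
#' @return A list with `assignment` (a [cluster_assignment()]) and
#'   `embedding` (the coordinate matrix the clusters live in).
#' @export
umap_cluster <- function(fps, n_clusters, n_neighbors = 15L, min_dist = 0.1,
                         n_components = 2L, metric = "jaccard", seed = 42L) {
  emb <- umap_embed(fps, n_neighbors = n_neighbors, min_dist = min_dist,
                    n_components = n_components, metric = metric, seed = seed)
  cl <- agglomerative_on_embedding(emb, n_clusters)
  cl$params <- c(cl$params,
                 list(n_neighbors = n_neighbors, min_dist = min_dist,
                      seed = seed))
  list(assignment = cl, embedding = emb)
}
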