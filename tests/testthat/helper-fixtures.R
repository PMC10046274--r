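# Fixture builders used across the suite.

make_fps <- function(rows, ids = NULL) {
  fingerprint_set(do.call(rbind, rows), ids = ids)
}

random_fps <- function(n, n_bits = 64, density = 0.3, seed = 1) {
  set.seed(seed)
  bits <- matrix(as.integer(runif(n * n_bits) < density), n, n_bits)
  # avoid all-zero rows so similarity oracles stay non-degenerate
  empty <- rowSums(bits) == 0
  bits[empty, 1] <- 1L
  fingerprint_set(bits)
}

# dist object with prescribed pairwise Tanimoto similarities (for clustering
# operations that consume distances directly).
sim_dist <- function(S, ids = NULL) {
  stats::as.dist(1 - S) |>
    (\(d) { attr(d, "Labels") <- ids %||% as.character(seq_len(nrow(S))); d })()
}

`%||%` <- function(x, y) if (is.null(x)) y else x

n_distinct_clusters <- function(cl) max(cl$labels)

planted_fps <- function(K = 4, m = 100, eps_off = 0.1, eps_on = 0.005,
                        seed = 1, n_outliers = 0, outlier_density = 0.05,
                        n_bits = 1024, density = 0.05) {
  generate_planted_fingerprints(synthetic_spec(
    n_clusters = K, members_per_cluster = m, n_bits = n_bits,
    density = density, eps_off = eps_off, eps_on = eps_on,
    n_outliers = n_outliers, outlier_density = outlier_density, seed = seed
  ))
}
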