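#' Specification of a synthetic fingerprint library
#'
#' Describes a planted-cluster generator for sparse binary fingerprints: each
#' of `n_clusters` clusters gets an independent centroid fingerprint whose
#' bits are on with probability `density`, and every member is the centroid
#' perturbed by bit-flip noise (`eps_off` = probability an on-bit is cleared,
#' `eps_on` = probability an off-bit is set). Optional outlier molecules are
#' independent random fingerprints with on-probability `outlier_density`,
#' unrelated to any centroid, so their nearest-neighbour similarity is
#' stochastically far below that of cluster members.
#'
#' The defaults (4 clusters of 100 molecules, 1024 bits, density 0.05,
#' `eps_off = 0.1`, `eps_on = 0.005`) give within-cluster Tanimoto
#' similarities around 0.7 — the similarity regime of a screening library of
#' related analogue series.
#'
#' @param n_clusters Number of planted clusters K.
#' @param members_per_cluster Molecules per cluster (scalar or length-K).
#' @param n_bits Fingerprint length (default 1024).
#' @param density Centroid on-bit probability, in (0, 1).
#' @param eps_off,eps_on Bit-flip noise rates, each in `[0, 1]`; scalar or
#'   length-K vectors for clusters of heterogeneous tightness.
#' @param n_outliers Number of injected outlier molecules.
#' @param outlier_density On-bit probability of outlier fingerprints.
#' @param seed Mandatory random seed for the single generator stream.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_clusters = 4L, members_per_cluster = 100L,
                           n_bits = 1024L, density = 0.05,
                           eps_off = 0.1, eps_on = 0.005,
                           n_outliers = 0L, outlier_density = 0.05,
                           seed = 1L) {
  if (n_clusters < 1) abort_validation("`n_clusters` must be >= 1.")
  if (density <= 0 || density >= 1) {
    abort_validation("`density` must lie strictly inside (0, 1).")
  }
  if (any(eps_off < 0 | eps_off > 1) || any(eps_on < 0 | eps_on > 1)) {
    abort_validation("noise rates must lie in [0, 1].")
  }
  if (n_outliers < 0) abort_validation("`n_outliers` must be >= 0.")
  members <- rep_len(as.integer(members_per_cluster), n_clusters)
  eps_off <- rep_len(eps_off, n_clusters)
  eps_on <- rep_len(eps_on, n_clusters)
  structure(
    list(n_clusters = as.integer(n_clusters), members_per_cluster = members,
         n_bits = as.integer(n_bits), density = density,
         eps_off = eps_off, eps_on = eps_on,
         n_outliers = as.integer(n_outliers),
         outlier_density = outlier_density, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generator preset emulating a large screening panel
#'
#' A frozen parameter set whose nearest-neighbour similarity distribution
#' mimics a heterogeneous screening library: many analogue clusters of
#' varying tightness plus a substantial fraction of structurally isolated
#' molecules, so that the median nearest-neighbour Tanimoto similarity falls
#' near 0.6 before outlier filtering and near 0.7 after filtering at a 0.5
#' cutoff. Calibrated once by simulation and kept fixed.
#'
#' @param n_per_cluster Molecules per planted cluster (default 40).
#' @param seed Random seed.
#' @return A `synthetic_spec`.
#' @export
nci60_like_spec <- function(n_per_cluster = 40L, seed = 1L) {
  synthetic_spec(
    n_clusters = 8L, members_per_cluster = n_per_cluster, n_bits = 1024L,
    density = 0.05, eps_off = rep(c(0.05, 0.20), each = 4L), eps_on = 0.008,
    n_outliers = as.integer(round(0.5 * 8L * n_per_cluster)),
    outlier_density = 0.05, seed = seed
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_spec> %d clusters x {%s} members, %d bits, ",
                     "density %.3g,\n  noise (off %s, on %s), %d outliers ",
                     "(density %.3g), seed %d\n"),
              x$n_clusters, paste(unique(x$members_per_cluster), collapse = ","),
              x$n_bits, x$density,
              paste(unique(signif(x$eps_off, 3)), collapse = "/"),
              paste(unique(signif(x$eps_on, 3)), collapse = "/"),
              x$n_outliers, x$outlier_density, x$seed))
  invisible(x)
}

rbinom_bits <- function(n, p) {
  matrix(as.integer(stats::runif(n[1] * n[2]) < p), n[1], n[2])
}

#' Generate a planted-cluster fingerprint set
#'
#' Draws K centroid fingerprints and perturbs each into its cluster members
#' according to the spec's bit-flip noise; then appends the spec's outliers
#' via [inject_outliers()]. Deterministic given the spec (a single seeded
#' random stream).
#'
#' @param spec A [synthetic_spec()].
#' @return A [fingerprint_set()] with `labels_true` populated (cluster labels
#'   `"1", "2", ...` and `"outlier"` for injected outliers).
#' @export
generate_planted_fingerprints <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  rows <- list(); labels <- character(0)
  for (q in seq_len(spec$n_clusters)) {
    centroid <- rbinom_bits(c(1, spec$n_bits), spec$density)
    m <- spec$members_per_cluster[q]
    members <- matrix(rep(centroid, each = m), m, spec$n_bits)
    flip_off <- rbinom_bits(c(m, spec$n_bits), spec$eps_off[q])
    flip_on <- rbinom_bits(c(m, spec$n_bits), spec$eps_on[q])
    members <- ifelse(members == 1L, 1L - flip_off, flip_on)
    rows[[q]] <- members
    labels <- c(labels, rep(as.character(q), m))
  }
  bits <- do.call(rbind, rows)
  storage.mode(bits) <- "integer"
  fps <- fingerprint_set(bits, ids = sprintf("syn%04d", seq_len(nrow(bits))),
                         radius = NA_integer_, labels_true = labels)
  if (spec$n_outliers > 0) {
    fps <- inject_outliers(fps, spec$n_outliers, spec$outlier_density,
                           seed = NULL)
  }
  fps
}

#' Append random outlier fingerprints to a set
#'
#' Outliers are independent random fingerprints (each bit on with probability
#' `outlier_density`) with no relation to any planted centroid; their
#' `labels_true` entry is the sentinel `"outlier"`.
#'
#' @param fps A [fingerprint_set()].
#' @param n_outliers Number of outliers to append (>= 0).
#' @param outlier_density On-bit probability.
#' @param seed Random seed, or `NULL` to continue the current stream (used
#'   internally by [generate_planted_fingerprints()]).
#' @return A `fingerprint_set` with `n_outliers` extra molecules appended.
#' @export
inject_outliers <- function(fps, n_outliers, outlier_density = 0.05,
                            seed = 1L) {
  stopifnot(is_fingerprint_set(fps))
  if (n_outliers < 0) abort_validation("`n_outliers` must be >= 0.")
  if (n_outliers == 0) return(fps)
  if (!is.null(seed)) set.seed(seed)
  extra <- rbinom_bits(c(n_outliers, fps$n_bits), outlier_density)
  labels <- fps$labels_true %||% rep(NA_character_, nrow(fps$bits))
  fingerprint_set(
    rbind(fps$bits, extra),
    ids = c(fps$ids, sprintf("out%04d", seq_len(n_outliers))),
    radius = fps$radius,
    labels_true = c(labels, rep("outlier", n_outliers))
  )
}

#' Write the planted truth table of a synthetic set
#'
#' @param fps A [fingerprint_set()] with `labels_true`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(fps, path) {
  stopifnot(is_fingerprint_set(fps))
  if (is.null(fps$labels_true)) abort_validation("no planted labels present.")
  readr::write_tsv(tibble::tibble(
    id = fps$ids, true_label = fps$labels_true,
    is_outlier = fps$labels_true == "outlier"
  ), path)
  invisible(path)
}
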