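#' Configure a full clustering comparison run
#'
#' Bundles every choice of the comparison protocol: which clustering methods
#' to run, their cutoff/cluster-number grids, the outlier cutoff separating
#' the two scenarios ("all molecules" vs "non-outlier molecules"), the UMAP
#' settings, and the seed. The default grids follow the protocol used for
#' large screening panels: Ward linkage cutoffs 0.5-3.0 in steps of 0.5 and
#' Taylor-Butina similarity cutoffs 0.35, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95,
#' 0.97, 0.99.
#'
#' @param methods Subset of `c("ward", "butina", "umap")`.
#' @param outlier_cutoff Nearest-neighbour similarity cutoff of the outlier
#'   filter (default 0.5).
#' @param ward_cutoffs Linkage-height cutoffs for the Ward route.
#' @param butina_cutoffs Similarity cutoffs for the Taylor-Butina route.
#' @param umap_k Cluster numbers requested from the embedding route.
#' @param n_neighbors,min_dist UMAP embedding settings.
#' @param seed Seed for the embedding.
#' @param block_size Block size of the pairwise passes.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(methods = c("ward", "butina", "umap"),
                            outlier_cutoff = 0.5,
                            ward_cutoffs = seq(0.5, 3.0, by = 0.5),
                            butina_cutoffs = c(0.35, 0.5, 0.6, 0.7, 0.8,
                                               0.9, 0.95, 0.97, 0.99),
                            umap_k = c(7L, 20L),
                            n_neighbors = 15L, min_dist = 0.0,
                            seed = 42L, block_size = 256L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(methods) == 0) abort_validation("enable at least one method.")
  if (any(butina_cutoffs <= 0 | butina_cutoffs > 1)) {
    abort_validation("Butina cutoffs must lie in (0, 1].")
  }
  if (any(ward_cutoffs <= 0)) {
    abort_validation("Ward cutoffs must be positive linkage heights.")
  }
  structure(
    list(methods = methods, outlier_cutoff = outlier_cutoff,
         ward_cutoffs = ward_cutoffs, butina_cutoffs = butina_cutoffs,
         umap_k = as.integer(umap_k), n_neighbors = as.integer(n_neighbors),
         min_dist = min_dist, seed = as.integer(seed),
         block_size = as.integer(block_size)),
    class = "pipeline_config"
  )
}

run_methods_on <- function(fps, config, scenario) {
  d <- NULL
  need_dist <- any(c("ward", "butina") %in% config$methods)
  if (need_dist) d <- tanimoto_distance(fps, block_size = config$block_size)

  rows <- list(); assignments <- list()
  if ("ward" %in% config$methods) {
    tree <- ward_linkage(d)
    for (co in config$ward_cutoffs) {
      cl <- cut_tree(tree, height_cutoff = co)
      q <- quality_report(fps, cl)
      rows[[length(rows) + 1]] <- dplyr::mutate(
        q, scenario = scenario, cutoff = co, .before = 1)
      assignments[[sprintf("%s_ward_%g", scenario, co)]] <- cl
    }
  }
  if ("butina" %in% config$methods) {
    for (co in config$butina_cutoffs) {
      cl <- butina_cluster(d, similarity_cutoff = co)
      q <- quality_report(fps, cl)
      rows[[length(rows) + 1]] <- dplyr::mutate(
        q, scenario = scenario, cutoff = co, .before = 1)
      assignments[[sprintf("%s_butina_%g", scenario, co)]] <- cl
    }
  }
  if ("umap" %in% config$methods) {
    emb <- umap_embed(fps, n_neighbors = config$n_neighbors,
                      min_dist = config$min_dist, seed = config$seed)
    for (k in config$umap_k) {
      cl <- agglomerative_on_embedding(emb, k)
      q <- quality_report(emb, cl)
      rows[[length(rows) + 1]] <- dplyr::mutate(
        q, scenario = scenario, cutoff = NA_real_, .before = 1)
      assignments[[sprintf("%s_umap_k%d", scenario, k)]] <- cl
    }
  }
  list(quality = dplyr::bind_rows(rows), assignments = assignments)
}

#' Run the full clustering comparison protocol
#'
#' Executes both scenarios — all molecules, and non-outlier molecules after
#' filtering at the configured nearest-neighbour cutoff — for every enabled
#' method and cutoff, scores each clustering with the three validity indices,
#' and assembles per-scenario quality tables, cluster-size summaries, average
#' similarity matrices of the best run per method, and a final comparison
#' table. When `out_dir` is given, every table is also written as TSV/CSV.
#'
#' @param fps A [fingerprint_set()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for report files.
#' @return A list of class `pipeline_result` with elements `quality`
#'   (tibble of all runs), `comparison` (best run per method and scenario),
#'   `outliers` (the [flag_outliers()] report), `sizes` (cluster-size
#'   summaries of the comparison rows), `similarity_matrices`, `assignments`
#'   and `config`.
#' @export
run_pipeline <- function(fps, config = pipeline_config(), out_dir = NULL) {
  stopifnot(is_fingerprint_set(fps), inherits(config, "pipeline_config"))
  profile <- nearest_neighbor_profile(fps, block_size = config$block_size)
  outrep <- flag_outliers(profile, config$outlier_cutoff)
  if (length(outrep$retained_ids) < 2) {
    abort_validation("outlier filter removed (almost) every molecule.")
  }
  kept <- fps[outrep$retained_ids]

  scen <- list(all = run_methods_on(fps, config, "all"),
               non_outlier = run_methods_on(kept, config, "non_outlier"))
  quality <- dplyr::bind_rows(scen$all$quality, scen$non_outlier$quality)
  assignments <- c(scen$all$assignments, scen$non_outlier$assignments)
  comparison <- comparison_table(quality)

  sizes <- purrr::map_dfr(seq_len(nrow(comparison)), function(i) {
    key <- assignment_key(comparison[i, ])
    dplyr::bind_cols(comparison[i, c("scenario", "method", "cutoff")],
                     cluster_size_summary(assignments[[key]]))
  })
  simmats <- purrr::map(seq_len(nrow(comparison)), function(i) {
    key <- assignment_key(comparison[i, ])
    src <- if (comparison$scenario[i] == "all") fps else kept
    average_similarity_matrix(src, assignments[[key]],
                              block_size = config$block_size)
  })
  names(simmats) <- vapply(seq_len(nrow(comparison)),
                           function(i) assignment_key(comparison[i, ]),
                           character(1))

  result <- structure(
    list(quality = quality, comparison = comparison, outliers = outrep,
         sizes = sizes, similarity_matrices = simmats,
         assignments = assignments, profile = profile, config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

assignment_key <- function(row) {
  if (row$method == "umap_agglomerative") {
    sprintf("%s_umap_k%d", row$scenario, row$n_clusters)
  } else {
    sprintf("%s_%s_%g", row$scenario, row$method, row$cutoff)
  }
}

#' Best-run comparison table across methods
#'
#' Reduces a table of scored clustering runs to one row per method and
#' scenario — the run with the best (maximal) silhouette — and flags the best
#' value of each metric per scenario (max silhouette, max Calinski-Harabasz,
#' min Davies-Bouldin). Rows with missing metrics never win a flag.
#'
#' @param quality A tibble of quality rows (as produced by [run_pipeline()]
#'   or [quality_report()] with added `scenario`/`cutoff` columns).
#' @return A tibble with one row per (scenario, method) and logical columns
#'   `best_silhouette`, `best_ch`, `best_db`.
#' @export
comparison_table <- function(quality) {
  stopifnot(is.data.frame(quality), nrow(quality) >= 1)
  if (!"scenario" %in% names(quality)) quality$scenario <- "all"
  flag_best <- function(x, pick_max = TRUE) {
    if (all(is.na(x))) return(rep(FALSE, length(x)))
    target <- if (pick_max) max(x, na.rm = TRUE) else min(x, na.rm = TRUE)
    !is.na(x) & x == target
  }
  quality |>
    dplyr::group_by(.data$scenario, .data$method) |>
    dplyr::arrange(dplyr::desc(.data$silhouette), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$scenario) |>
    dplyr::mutate(
      best_silhouette = flag_best(.data$silhouette),
      best_ch = flag_best(.data$calinski_harabasz),
      best_db = flag_best(.data$davies_bouldin, pick_max = FALSE)
    ) |>
    dplyr::ungroup()
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d runs, %d removed as outliers (cutoff %.2g)\n",
              nrow(x$quality), x$outliers$n_removed, x$outliers$cutoff))
  print(x$comparison)
  invisible(x)
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$quality, file.path(out_dir, "quality.tsv"))
  readr::write_tsv(result$comparison, file.path(out_dir, "comparison.tsv"))
  readr::write_tsv(result$sizes, file.path(out_dir, "cluster_sizes.tsv"))
  readr::write_tsv(tidy(result$outliers), file.path(out_dir, "outliers.tsv"))
  readr::write_tsv(result$profile, file.path(out_dir, "nn_profile.tsv"))
  for (key in names(result$similarity_matrices)) {
    write_avg_sim_matrix(result$similarity_matrices[[key]],
                         file.path(out_dir, sprintf("simmatrix_%s.csv", key)))
  }
  for (key in names(result$assignments)) {
    write_cluster_assignment(result$assignments[[key]],
                             file.path(out_dir, sprintf("clusters_%s.tsv", key)))
  }
  invisible(out_dir)
}
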