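test_that("noise-free clusters are internally identical", {
  fps <- planted_fps(K = 3, m = 5, eps_off = 0, eps_on = 0, seed = 1,
                     n_bits = 256)
  S <- naive_similarity_matrix(fps$bits)
  for (q in c("1", "2", "3")) {
    members <- which(fps$labels_true == q)
    expect_true(all(S[members, members] == 1))
  }
})

test_that("generation is deterministic given the spec", {
  spec <- synthetic_spec(n_clusters = 2, members_per_cluster = 10,
                         n_outliers = 3, seed = 33)
  a <- generate_planted_fingerprints(spec)
  b <- generate_planted_fingerprints(spec)
  expect_identical(a$bits, b$bits)
  expect_identical(a$labels_true, b$labels_true)
})

test_that("within-cluster similarity matches a Monte-Carlo oracle of the noise model", {
  # package route: mean within-cluster similarity pooled over many centroids
  # (~1000 member pairs), so centroid-level sampling noise averages out
  fps <- planted_fps(K = 22, m = 10, eps_off = 0.1, eps_on = 0.005,
                     seed = 1, n_bits = 1024, density = 0.05)
  S <- naive_similarity_matrix(fps$bits)
  within <- unlist(lapply(unique(fps$labels_true), function(q) {
    i <- which(fps$labels_true == q)
    S[i, i][upper.tri(S[i, i])]
  }))
  observed <- mean(within)

  # independent oracle: directly simulate member pairs from one centroid
  set.seed(1)
  sims <- replicate(1000, {
    centroid <- runif(1024) < 0.05
    perturb <- function() {
      x <- centroid
      x[centroid] <- runif(sum(centroid)) >= 0.1          # keep prob 0.9
      x[!centroid] <- runif(sum(!centroid)) < 0.005
      x
    }
    a <- perturb(); b <- perturb()
    sum(a & b) / sum(a | b)
  })
  expect_equal(observed, mean(sims), tolerance = 0.02)
})

test_that("outlier injection appends exactly what it promises", {
  fps <- planted_fps(K = 2, m = 5, seed = 2, n_bits = 128)
  expect_identical(inject_outliers(fps, 0), fps)
  out <- inject_outliers(fps, 4, outlier_density = 0.05, seed = 3)
  expect_equal(nrow(out$bits), 14)
  expect_equal(sum(out$labels_true == "outlier"), 4)
  expect_identical(out$bits[1:10, ], fps$bits)
})

test_that("planted outliers have stochastically lower nn similarity than members", {
  fps <- planted_fps(K = 4, m = 25, eps_off = 0.1, eps_on = 0.005,
                     n_outliers = 15, seed = 4, n_bits = 512)
  prof <- nearest_neighbor_profile(fps)
  is_out <- fps$labels_true == "outlier"
  test <- stats::wilcox.test(prof$nn_sim[is_out], prof$nn_sim[!is_out],
                             alternative = "less", exact = FALSE)
  expect_lt(test$p.value, 1e-6)
})

test_that("the screening-panel preset reproduces the target similarity profile", {
  fps <- generate_planted_fingerprints(nci60_like_spec(seed = 1))
  prof <- nearest_neighbor_profile(fps)
  pre_median <- stats::median(prof$nn_sim)
  retained <- prof$nn_sim[prof$nn_sim > 0.5]
  post_median <- stats::median(retained)
  expect_gt(pre_median, 0.55)
  expect_lt(pre_median, 0.65)
  expect_gt(post_median, 0.65)
  expect_lt(post_median, 0.75)
})

test_that("truth tables serialise the planted structure", {
  fps <- planted_fps(K = 2, m = 3, n_outliers = 1, seed = 5, n_bits = 64)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth_table(fps, f)
  truth <- readr::read_tsv(f, col_types = "ccl", progress = FALSE)
  expect_equal(nrow(truth), 7)
  expect_equal(sum(truth$is_outlier), 1)
  expect_error(write_truth_table(random_fps(3), f),
               class = "molclust_validation_error")
})

test_that("invalid generator parameters are rejected", {
  expect_error(synthetic_spec(density = 0), class = "molclust_validation_error")
  expect_error(synthetic_spec(eps_off = 1.2), class = "molclust_validation_error")
  expect_error(synthetic_spec(n_clusters = 0), class = "molclust_validation_error")
  expect_error(inject_outliers(random_fps(3), -1),
               class = "molclust_validation_error")
})
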