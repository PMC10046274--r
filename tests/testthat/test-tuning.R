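test_that("a single-cell grid wins all three metrics", {
  fps <- planted_fps(K = 3, m = 25, eps_off = 0.08, eps_on = 0.004,
                     seed = 21, n_bits = 256)
  gs <- grid_search_umap(fps, neighbor_values = 10, min_dist_values = 0,
                         fixed_k = 3, seed = 1)
  expect_equal(nrow(gs$results), 1)
  expect_equal(gs$winner$wins, 3L)
  expect_equal(gs$winner$n_neighbors, 10)
  expect_error(grid_search_umap(fps, integer(0), 0, 3),
               class = "molclust_validation_error")
})

test_that("the grid winner is invariant to the order the grid is supplied in", {
  fps <- planted_fps(K = 3, m = 20, eps_off = 0.1, eps_on = 0.005,
                     seed = 22, n_bits = 256)
  g1 <- grid_search_umap(fps, c(8, 15), c(0, 0.5), fixed_k = 3, seed = 2)
  g2 <- grid_search_umap(fps, c(15, 8), c(0.5, 0), fixed_k = 3, seed = 2)
  expect_equal(g1$winner$n_neighbors, g2$winner$n_neighbors)
  expect_equal(g1$winner$min_dist, g2$winner$min_dist)
  expect_lte(max(g1$results$wins, na.rm = TRUE), 3)
})

test_that("distortion curves are non-increasing and find the planted elbow", {
  # three well-separated blobs: the drop completes at k = 3 and the curve is
  # flat beyond, which is the regime where a distortion knee is well-defined
  set.seed(0)
  blobs <- rbind(matrix(rnorm(60, 0, 0.4), ncol = 2),
                 matrix(rnorm(60, 10, 0.4), ncol = 2),
                 cbind(rnorm(30, 0, 0.4), rnorm(30, 18, 0.4)))
  ec <- elbow_curve(blobs, 2:8, scoring = "distortion")
  expect_true(all(diff(ec$score) <= 1e-9))
  expect_equal(detect_knee(ec), 3L)
})

test_that("knee detection on a 7-cluster library picks 7", {
  fps <- planted_fps(K = 7, m = 25, eps_off = 0.05, eps_on = 0.002,
                     seed = 0, n_bits = 512)
  ec <- elbow_curve(fps$bits + 0, 2:15, scoring = "distortion")
  expect_equal(detect_knee(ec), 7L)
})

test_that("degenerate and linear curves have no knee", {
  flat <- structure(list(k = 2:8, score = rep(5, 7), scoring = "distortion"),
                    class = "elbow_curve")
  expect_true(is.na(detect_knee(flat)))
  linear <- structure(list(k = 2:8, score = seq(70, 10, by = -10),
                           scoring = "distortion"), class = "elbow_curve")
  expect_true(is.na(detect_knee(linear)))
  short <- structure(list(k = 2:3, score = c(2, 1), scoring = "distortion"),
                     class = "elbow_curve")
  expect_error(detect_knee(short), class = "molclust_validation_error")

  # constant data: distortion identically zero at every k
  const <- matrix(1, 10, 2)
  ec0 <- elbow_curve(const, 2:5, scoring = "distortion")
  expect_equal(ec0$score, rep(0, 4))
  expect_true(is.na(detect_knee(ec0)))
})

test_that("knee detection is invariant to positive rescaling of the scores", {
  set.seed(3)
  blobs <- rbind(matrix(rnorm(40, 0, 0.5), ncol = 2),
                 matrix(rnorm(40, 6, 0.5), ncol = 2),
                 cbind(rnorm(20, 0, 0.5), rnorm(20, 12, 0.5)))
  ec <- elbow_curve(blobs, 2:8, scoring = "distortion")
  scaled <- ec
  scaled$score <- ec$score * 1e6
  expect_equal(detect_knee(ec), detect_knee(scaled))
})

test_that("silhouette scoring stays within [-1, 1] and selects the argmax", {
  set.seed(4)
  blobs <- rbind(matrix(rnorm(50, 0, 0.5), ncol = 2),
                 matrix(rnorm(50, 7, 0.5), ncol = 2))
  ec <- elbow_curve(blobs, 2:6, scoring = "silhouette")
  expect_true(all(ec$score >= -1 & ec$score <= 1))
  expect_equal(detect_knee(ec), ec$k[which.max(ec$score)])
  expect_equal(detect_knee(ec), 2L)
  expect_error(elbow_curve(blobs, c(3, 2)),
               class = "molclust_validation_error")
  expect_error(elbow_curve(blobs, 2:60),
               class = "molclust_validation_error")
})
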