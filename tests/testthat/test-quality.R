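test_that("silhouette matches hand-evaluated cases", {
  # clusters {0,1} and {5,6}: per-point SC 0.8182, 0.7778, 0.7778, 0.8182
  pts <- matrix(c(0, 1, 5, 6), ncol = 1)
  labels <- c(1, 1, 2, 2)
  res <- silhouette_mean(pts, labels)
  expect_equal(res$terms$sc, c(9 / 11, 7 / 9, 7 / 9, 9 / 11), tolerance = 1e-12)
  expect_equal(res$score, mean(c(9 / 11, 7 / 9, 7 / 9, 9 / 11)),
               tolerance = 1e-12)

  # zero within-cluster spread, positive between: perfect score
  tight <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_equal(silhouette_mean(tight, c(1, 1, 2, 2))$score, 1)

  # a singleton contributes 0 by convention
  res3 <- silhouette_mean(matrix(c(0, 1, 9), ncol = 1), c(1, 1, 2))
  expect_equal(res3$terms$sc[3], 0)
  expect_error(silhouette_mean(pts, rep(1, 4)),
               class = "molclust_validation_error")
  # all singletons: defined as 0 by convention
  expect_equal(silhouette_mean(pts, 1:4)$score, 0)
})

test_that("silhouette accepts precomputed distances and matches the matrix route", {
  fps <- random_fps(40, seed = 17)
  labels <- rep(1:4, each = 10)
  d <- tanimoto_distance(fps)
  expect_equal(silhouette_mean(d, labels)$score,
               naive_silhouette(as.matrix(d), labels), tolerance = 1e-12)
})

test_that("calinski-harabasz matches the dispersion-trace definition", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  res <- calinski_harabasz(pts, c(1, 1, 2, 2))
  expect_equal(res$tr_W, 1)
  expect_equal(res$tr_B, 100)
  expect_equal(res$score, 200)

  expect_error(calinski_harabasz(pts, rep(1, 4)),
               class = "molclust_validation_error")
  expect_warning(res2 <- calinski_harabasz(matrix(c(0, 10), ncol = 1),
                                           c(1, 2)), "Inf")
  expect_equal(res2$score, Inf)
})

test_that("davies-bouldin matches the centroid-scatter definition", {
  pts <- matrix(c(0, 2, 10, 12), ncol = 1)
  res <- davies_bouldin(pts, c(1, 1, 2, 2))
  expect_equal(res$s, c(1, 1))
  expect_equal(res$score, 0.2)

  # identical point clouds in two clusters: coincident centroids
  dup <- matrix(c(0, 2, 0, 2), ncol = 1)
  expect_equal(davies_bouldin(dup, c(1, 1, 2, 2))$score, Inf)

  # collapsed clusters at distinct locations: the minimum score, zero
  coll <- matrix(c(0, 0, 7, 7), ncol = 1)
  expect_equal(davies_bouldin(coll, c(1, 1, 2, 2))$score, 0)
  expect_error(davies_bouldin(pts, rep(1, 4)),
               class = "molclust_validation_error")
})

test_that("all three indices match naive oracles on random instances", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(20:80, 1)
    k <- sample(2:6, 1)
    pts <- matrix(rnorm(n * 3, sd = 2), n)
    labels <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
    D <- as.matrix(stats::dist(pts))
    expect_equal(silhouette_mean(pts, labels)$score,
                 naive_silhouette(D, labels), tolerance = 1e-9)
    expect_equal(calinski_harabasz(pts, labels)$score,
                 naive_ch(pts, labels), tolerance = 1e-9)
    expect_equal(davies_bouldin(pts, labels)$score,
                 naive_db(pts, labels), tolerance = 1e-9)
  }
})

test_that("silhouette agrees with the cluster-package reference", {
  fps <- random_fps(50, seed = 23)
  labels <- rep(1:5, each = 10)
  d <- tanimoto_distance(fps)
  ref <- mean(cluster::silhouette(labels, d)[, "sil_width"])
  expect_equal(silhouette_mean(d, labels)$score, ref, tolerance = 1e-9)
})

test_that("within- plus between-cluster scatter equals total scatter", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    k <- sample(2:5, 1)
    pts <- matrix(rnorm(n * 4), n)
    labels <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
    res <- calinski_harabasz(pts, labels)
    total <- sum(sweep(pts, 2, colMeans(pts))^2)
    expect_equal(res$tr_W + res$tr_B, total, tolerance = 1e-9)
  }
})

test_that("average similarity matrix enumerates pairs correctly", {
  # two clusters of two identical molecules, zero cross-similarity
  bits <- rbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L),
                c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L))
  asm <- average_similarity_matrix(fingerprint_set(bits), c(1, 1, 2, 2))
  expect_equal(diag(asm$matrix), c(1, 1))
  expect_equal(asm$matrix[1, 2], 0)

  # singleton diagonals are missing, off-diagonal is the single pair value
  bits2 <- rbind(c(1L, 1L, 1L, 0L, 0L), c(1L, 1L, 0L, 1L, 1L))
  s <- tanimoto(bits2[1, ], bits2[2, ])
  asm2 <- average_similarity_matrix(fingerprint_set(bits2), c(1, 2))
  expect_true(all(is.na(diag(asm2$matrix))))
  expect_equal(asm2$matrix[2, 1], s)

  # mixed sizes: diag(A) = s12, off(A,B) = (s13 + s23) / 2, diag(B) missing
  bits3 <- rbind(c(1L, 1L, 1L, 1L, 0L, 0L), c(1L, 1L, 1L, 0L, 1L, 0L),
                 c(1L, 0L, 0L, 0L, 0L, 1L))
  fps3 <- fingerprint_set(bits3)
  s12 <- tanimoto(bits3[1, ], bits3[2, ])
  s13 <- tanimoto(bits3[1, ], bits3[3, ])
  s23 <- tanimoto(bits3[2, ], bits3[3, ])
  asm3 <- average_similarity_matrix(fps3, c(1, 1, 2))
  expect_equal(asm3$matrix[1, 1], s12)
  expect_true(is.na(asm3$matrix[2, 2]))
  expect_equal(asm3$matrix[1, 2], (s13 + s23) / 2)
  expect_equal(asm3$matrix[1, 2], asm3$matrix[2, 1])
})

test_that("average similarity matrix matches a naive pair enumeration", {
  fps <- random_fps(35, n_bits = 48, seed = 31)
  labels <- c(1:4, sample(1:4, 31, replace = TRUE))
  asm <- average_similarity_matrix(fps, labels, block_size = 11)
  S <- naive_similarity_matrix(fps$bits)
  for (p in 1:4) {
    for (q in 1:4) {
      ip <- which(labels == p); iq <- which(labels == q)
      if (p == q) {
        pairs <- utils::combn(ip, 2)
        expected <- mean(S[t(pairs)])
        expect_equal(asm$matrix[p, p], expected, tolerance = 1e-12)
      } else {
        expect_equal(asm$matrix[p, q], mean(S[ip, iq]), tolerance = 1e-12)
      }
    }
  }
})

test_that("diagonal dominance holds on well-separated planted clusters", {
  fps <- planted_fps(K = 4, m = 20, eps_off = 0.1, eps_on = 0.005,
                     seed = 18, n_bits = 512)
  cl <- cut_tree(ward_linkage(tanimoto_distance(fps)), k = 4)
  asm <- average_similarity_matrix(fps, cl)
  m <- asm$matrix
  for (i in seq_len(nrow(m))) {
    off <- m[i, -i]
    expect_true(all(m[i, i] > off))
  }
})

test_that("perfect planted silhouette beats a random relabelling", {
  fps <- planted_fps(K = 3, m = 20, eps_off = 0.1, eps_on = 0.005,
                     seed = 19, n_bits = 512)
  truth <- as.integer(fps$labels_true)
  set.seed(1)
  shuffled <- sample(truth)
  pts <- fps$bits + 0
  expect_gt(silhouette_mean(pts, truth)$score,
            silhouette_mean(pts, shuffled)$score)
})

test_that("cluster size summaries report the documented statistics", {
  s <- cluster_size_summary(c(1, 2, 3, 3))  # sizes 1, 1, 2
  expect_equal(s$min, 1)
  expect_equal(s$max, 2)
  expect_equal(s$mean, 4 / 3, tolerance = 1e-12)
  expect_equal(s$n_clusters, 3)

  s2 <- cluster_size_summary(rep(1:4, each = 5))  # sizes 5,5,5,5
  expect_equal(s2$std, 0)
  expect_equal(s2$p50, 5)

  cl <- cut_tree(ward_linkage(tanimoto_distance(random_fps(30, seed = 2))),
                 k = 6)
  s3 <- cluster_size_summary(cl)
  expect_equal(s3$mean * s3$n_clusters, 30)  # sizes sum to n
})

test_that("quality_report degrades to NA on degenerate clusterings", {
  fps <- random_fps(10, seed = 40)
  q <- quality_report(fps, rep(1L, 10))
  expect_true(is.na(q$silhouette) && is.na(q$calinski_harabasz))
  q2 <- quality_report(fps, 1:10)   # all singletons: CH undefined (k = n)
  expect_true(is.na(q2$calinski_harabasz))
  expect_equal(q2$silhouette, 0)
})
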