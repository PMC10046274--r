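# Independent naive-loop oracles: direct transcriptions of the definitions,
# kept deliberately separate from the package's vectorised implementations.

naive_tanimoto <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}

naive_similarity_matrix <- function(bits) {
  n <- nrow(bits)
  S <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- naive_tanimoto(bits[i, ], bits[j, ])
    }
  }
  S
}

# Eqs for the silhouette: a_i, b_i, SC(i), averaged; singleton SC = 0.
naive_silhouette <- function(D, labels) {
  n <- nrow(D)
  sc <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { sc[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- Inf
    for (J in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(D[i, labels == J]))
    }
    sc[i] <- (b - a) / max(a, b)
  }
  mean(sc)
}

# Variance-ratio criterion from the dispersion-trace definitions.
naive_ch <- function(points, labels) {
  k <- length(unique(labels))
  n <- nrow(points)
  grand <- colMeans(points)
  tr_W <- 0; tr_B <- 0
  for (q in unique(labels)) {
    member <- points[labels == q, , drop = FALSE]
    cq <- colMeans(member)
    for (r in seq_len(nrow(member))) tr_W <- tr_W + sum((member[r, ] - cq)^2)
    tr_B <- tr_B + nrow(member) * sum((cq - grand)^2)
  }
  (tr_B / tr_W) * (n - k) / (k - 1)
}

# Mean over clusters of the worst (s_i + s_j) / d_ij ratio.
naive_db <- function(points, labels) {
  ks <- sort(unique(labels))
  cent <- lapply(ks, function(q) colMeans(points[labels == q, , drop = FALSE]))
  s <- vapply(seq_along(ks), function(qi) {
    member <- points[labels == ks[qi], , drop = FALSE]
    mean(sqrt(rowSums(sweep(member, 2, cent[[qi]])^2)))
  }, numeric(1))
  worst <- vapply(seq_along(ks), function(i) {
    max(vapply(setdiff(seq_along(ks), i), function(j) {
      (s[i] + s[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
    }, numeric(1)))
  }, numeric(1))
  mean(worst)
}

# Brute-force greedy Ward agglomeration: clusters kept as explicit index
# sets, squared distances updated by the Lance-Williams recurrence, minimum
# found by a double loop. Returns merge heights in order plus the partition
# at any requested cluster count.
brute_ward <- function(d) {
  D <- as.matrix(d)^2
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (D[i, j] < best[1]) best <- c(D[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, sqrt(best[1]))
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    newD <- numeric(m)
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      nk <- length(clusters[[k]])
      newD[k] <- ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] -
                    nk * D[i, j]) / (ni + nj + nk)
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    D[i, ] <- newD; D[, i] <- newD; D[i, i] <- 0
    clusters <- clusters[-j]
    D <- D[-j, -j, drop = FALSE]
    partitions[[length(partitions) + 1]] <- clusters
  }
  list(heights = heights,
       partition_at = function(k) {
         cl <- partitions[[n - k]]
         labels <- integer(n)
         for (q in seq_along(cl)) labels[cl[[q]]] <- q
         labels
       })
}

# Chance-corrected partition agreement (independent of mclust, which some
# tests also use as a second route).
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
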