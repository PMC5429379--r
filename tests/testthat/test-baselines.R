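# 1-D instance with a known optimal 2-partition: {0, 0.1} vs {10, 10.1}
tiny_1d <- function() matrix(c(0, 0.1, 10, 10.1), ncol = 1)

test_that("k-means solves the hand instance and its sums of squares check out", {
  X <- tiny_1d()
  p <- kmeans_fit(X, 2, n_init = 10, seed = 1)
  expect_equal(sort(p$centroids[, 1]), c(0.05, 10.05))
  expect_equal(p$labels[1], p$labels[2])
  expect_equal(p$labels[3], p$labels[4])
  # exhaustive oracle over all 2-partitions confirms W is minimal
  best_w <- min(apply(expand.grid(rep(list(1:2), 4))[-c(1, 16), ], 1,
                      function(l) {
                        sum(unlist(lapply(split(X[, 1], l), function(v)
                          sum((v - mean(v))^2))))
                      }))
  expect_equal(p$W, best_w)
  expect_equal(p$W, 0.01)
  expect_equal(p$B, 100.00)
  expect_equal(p$W + p$B, p$TSS, tolerance = 1e-8)
})

test_that("k = n gives singleton clusters with zero scatter", {
  X <- matrix(stats::rnorm(15), ncol = 3)
  p <- make_partition(X, seq_len(5))
  expect_equal(p$W, 0)
  expect_equal(p$B, p$TSS)
})

test_that("labels are invariant under rigid rotation of the data", {
  blobs <- easy_blobs(30, seed = 31)
  set.seed(31)
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  p1 <- kmeans_fit(blobs$X, 3, n_init = 50, seed = 5)
  p2 <- kmeans_fit(blobs$X %*% Q, 3, n_init = 50, seed = 5)
  expect_equal(compare_partitions(p1$labels, p2$labels)$ari, 1)
  expect_error(kmeans_fit(blobs$X, nrow(blobs$X) + 1), "exceed")
})

test_that("W + B = TSS holds on fuzzed partitions", {
  set.seed(41)
  for (i in 1:15) {
    n <- sample(10:60, 1)
    X <- matrix(stats::rnorm(n * 3), ncol = 3)
    k <- sample(1:5, 1)
    labels <- sample(seq_len(k), n, replace = TRUE)
    labels[seq_len(k)] <- seq_len(k)  # keep every cluster non-empty
    p <- make_partition(X, labels)
    expect_equal(p$W + p$B, p$TSS, tolerance = 1e-8)
  }
})

test_that("the index scan reproduces hand-computed values on the 1-D case", {
  X <- tiny_1d()
  idx <- kmeans_index_scan(X, k_range = 2, n_init = 10, seed = 2,
                           distance_indices = FALSE)
  n <- 4
  expect_equal(idx$ch, (100.00 / 1) / (0.01 / (n - 2)))  # 20000
  expect_equal(idx$ch, 20000)
  expect_equal(idx$ball, 0.01 / 2)
  expect_equal(idx$explained_dissimilarity, 1 - 0.01 / 100.01)
  # Ball at k = 1 equals TSS
  p1 <- kmeans_fit(X, 1)
  expect_equal(p1$W / 1, p1$TSS)
})

test_that("explained dissimilarity spans its extremes", {
  X <- matrix(stats::rnorm(30), ncol = 3)
  expect_equal(explained_dissimilarity(X, make_partition(X, rep(1, 10))), 0)
  expect_equal(explained_dissimilarity(X, make_partition(X, 1:10)), 1)
  X0 <- matrix(1, 5, 3)
  expect_warning(e <- explained_dissimilarity(X0,
                                              make_partition(X0,
                                                             rep(1, 5))),
                 "degenerate")
  expect_equal(e, 1)
})

test_that("the CH criterion peaks at the true number of blobs", {
  hits <- vapply(1:10, function(s) {
    blobs <- easy_blobs(40, sd = 0.4, seed = s)
    idx <- kmeans_index_scan(blobs$X, k_range = 2:6, n_init = 20,
                             seed = s, distance_indices = FALSE)
    idx$k[which.max(idx$ch)] == 3
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("hierarchical clustering reproduces a hand-built ultrametric", {
  # A and B at distance 1; C at distance 2 from both (an ultrametric)
  X <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(4 - 0.25)))
  hc <- hclust_fit(X, linkage = "single", metric = "euclidean")
  expect_equal(hc$hclust$height, c(1, 2))
  expect_equal(cophenetic_correlation(hc), 1)
  p2 <- cut_dendrogram(hc, 2)
  expect_equal(p2$labels[1], p2$labels[2])
  expect_false(p2$labels[3] == p2$labels[1])
  expect_equal(cut_dendrogram(hc, 1)$k, 1L)
  expect_equal(cut_dendrogram(hc, 3)$k, 3L)
  expect_error(cut_dendrogram(hc, 4), "between 1")
})

test_that("duplicate points merge first at height zero; heights are monotone", {
  set.seed(43)
  X <- rbind(matrix(stats::rnorm(20), ncol = 2), c(0, 0), c(0, 0))
  hc <- hclust_fit(X, linkage = "single", metric = "euclidean")
  expect_equal(min(hc$hclust$height), 0)
  expect_true(all(diff(hc$hclust$height) >= -1e-12))
})

test_that("correlation distance groups stimuli by profile shape", {
  # two profile shapes (rising vs falling), far apart in level
  X <- rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1), c(6, 4, 2))
  hc <- hclust_fit(X, linkage = "average", metric = "correlation")
  p <- cut_dendrogram(hc, 2)
  expect_equal(p$labels[1], p$labels[2])
  expect_equal(p$labels[3], p$labels[4])
  expect_false(p$labels[1] == p$labels[3])
  # constant profiles trigger the degenerate-correlation warning
  expect_warning(hclust_fit(rbind(c(1, 1, 1), c(1, 2, 3), c(3, 2, 1)),
                            metric = "correlation"),
                 "zero-variance")
  expect_error(hclust_fit(matrix(1:4, ncol = 1), metric = "correlation"),
               "two variables")
})

test_that("internal indices separate well-split blobs and reject k = 1", {
  blobs <- make_blobs(25, rbind(c(0, 0, 0), c(20, 0, 0)), sd = 0.3,
                      seed = 47)
  p <- make_partition(blobs$X, blobs$labels)
  idx <- internal_indices(blobs$X, p)
  expect_gt(idx$silhouette, 0.9)
  expect_gt(idx$dunn, 1)
  expect_equal(idx$connectivity, 0)
  expect_error(internal_indices(blobs$X,
                                make_partition(blobs$X,
                                               rep(1, nrow(blobs$X)))),
               "undefined")
})
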