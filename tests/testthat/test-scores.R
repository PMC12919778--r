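test_that("silhouette reproduces hand-computed geometries", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(silhouetteScore(pts, c("A", "A", "B", "B")),
               (0.904762 + 0.894737 + 0.894737 + 0.904762) / 4,
               tolerance = 1e-6)
  # interleaved labels: per-point widths (-0.4, -0.5, -0.5, -0.4)
  expect_equal(silhouetteScore(matrix(c(0, 10, 1, 11), ncol = 1),
                               c("A", "A", "B", "B")), -0.45)
  # two singleton labels: convention s = 0
  expect_equal(silhouetteScore(matrix(c(0, 5), ncol = 1), c("A", "B")), 0)
  expect_error(silhouetteScore(pts, rep("A", 4)), "2 distinct")
})

test_that("adjusted Rand index reproduces the pair-counting examples", {
  expect_equal(adjustedRandIndex(c("A", "A", "B", "B"), c(1, 1, 2, 2)), 1.0)
  expect_equal(adjustedRandIndex(c("A", "A", "B", "B"), c(2, 2, 1, 1)), 1.0)
  # index 0, expected 2/3, max 2 -> -0.5
  expect_equal(adjustedRandIndex(c("A", "A", "B", "B"), c(1, 2, 1, 2)), -0.5)
})

test_that("kmeansARI recovers well-separated blobs for every seed", {
  set.seed(30)
  blobs <- rbind(matrix(rnorm(40, 0, 0.05), 20, 2),
                 matrix(rnorm(40, 10, 0.05), 20, 2))
  labels <- rep(c("x", "y"), each = 20)
  for (seed in 0:4)
    expect_equal(kmeansARI(blobs, labels, seed = seed), 1.0)
  # stats::kmeans agrees on this geometry (independent clustering oracle)
  km <- kmeans(blobs, 2, nstart = 5)
  expect_equal(adjustedRandIndex(km$cluster, labels), 1.0)
  expect_error(kmeansARI(matrix(0, 2, 2), c("a", "b", "c")), "length|labels")
})

test_that("knn preservation reproduces hand-built neighbour sets", {
  high <- matrix(c(0, 1, 3, 10), ncol = 1)
  low <- matrix(c(0, 10, 11, 20), ncol = 1)
  # high NN at k=1: (B, A, B, C); low: (B, C, B, C) -> 3/4 agree
  expect_equal(knnPreservation(high, low, k = 1), 0.75)
  expect_equal(knnPreservation(high, high, k = 2), 1.0)
  expect_equal(knnPreservation(high, low, k = 3), 1.0)  # k = n-1
  expect_error(knnPreservation(high, low[1:3, , drop = FALSE], k = 1),
               "same rows")
})

test_that("cpd reproduces hand-ranked distance vectors", {
  high <- matrix(c(0, 1, 3), ncol = 1)
  low <- matrix(c(0, 3, 4), ncol = 1)
  # rank vectors (1,3,2) vs (2,3,1): rho = 1 - 6*2/24
  expect_equal(cpdScore(high, low), 0.5)
  h2 <- matrix(c(0, 0, 1, 0, 0, 1), 3, byrow = TRUE)
  expect_equal(cpdScore(h2, 2 * h2[, 1:2]), 1.0)   # monotone transform
  # triangle whose distance ranks reverse between the two layouts
  highT <- rbind(c(0, 0), c(1, 0), c(0, 2))        # AB=1 < AC=2 < BC=sqrt(5)
  lowT <- rbind(c(0, 0), c(2, 0), c(1.9, 0.1))     # AB=2 > AC=1.9 > BC=0.14
  expect_equal(cpdScore(highT, lowT), -1)
  expect_error(cpdScore(high[1:2, , drop = FALSE],
                        low[1:2, , drop = FALSE]), "n >= 3")
})

test_that("all four scores agree with brute-force oracles on random instances", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(6:40, 1); p <- sample(2:5, 1)
    high <- matrix(rnorm(n * p), n, p)
    low <- matrix(rnorm(n * 2), n, 2)
    labels <- sample(letters[1:3], n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    k <- sample(seq_len(n - 1), 1)
    expect_equal(silhouetteScore(low, labels), oracleSilhouette(low, labels),
                 tolerance = 1e-8)
    expect_equal(knnPreservation(high, low, k), oracleKNN(high, low, k),
                 tolerance = 1e-8)
    expect_equal(cpdScore(high, low), oracleCPD(high, low), tolerance = 1e-8)
    part <- sample(1:4, n, replace = TRUE)
    expect_equal(adjustedRandIndex(labels, part), oracleARI(labels, part),
                 tolerance = 1e-8)
  }
})

test_that("ARI agrees with mclust and silhouette with cluster", {
  skip_if_not_installed("mclust")
  skip_if_not_installed("cluster")
  set.seed(32)
  for (rep in 1:10) {
    x <- sample(1:3, 25, replace = TRUE)
    y <- sample(1:3, 25, replace = TRUE)
    expect_equal(adjustedRandIndex(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
    pts <- matrix(rnorm(50), 25, 2)
    lab <- sample(c(1, 2), 25, replace = TRUE)
    if (length(unique(lab)) < 2) next
    sil <- cluster::silhouette(lab, dist(pts))
    expect_equal(silhouetteScore(pts, lab), mean(sil[, "sil_width"]),
                 tolerance = 1e-10)
  }
})

test_that("scores are invariant under a common permutation of items", {
  set.seed(33)
  n <- 25
  high <- matrix(rnorm(n * 4), n, 4)
  low <- matrix(rnorm(n * 2), n, 2)
  labels <- sample(c("a", "b", "c"), n, replace = TRUE)
  perm <- sample(n)
  expect_equal(silhouetteScore(low[perm, ], labels[perm]),
               silhouetteScore(low, labels), tolerance = 1e-12)
  expect_equal(knnPreservation(high[perm, ], low[perm, ], 5),
               knnPreservation(high, low, 5), tolerance = 1e-12)
  expect_equal(cpdScore(high[perm, ], low[perm, ]),
               cpdScore(high, low), tolerance = 1e-12)
  expect_equal(adjustedRandIndex(labels[perm], labels[perm]),
               adjustedRandIndex(labels, labels))
})

test_that("cpd and knn equal 1 under any similarity transform of a 2-D space", {
  set.seed(34)
  high <- matrix(rnorm(40), 20, 2)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  low <- 3.2 * high %*% R + matrix(rep(c(5, -2), each = 20), 20)
  expect_equal(cpdScore(high, low), 1.0, tolerance = 1e-12)
  expect_equal(knnPreservation(high, low, 5), 1.0)
})

test_that("ARI is near zero for independent random partitions", {
  set.seed(35)
  vals <- replicate(500, {
    adjustedRandIndex(sample(1:3, 30, replace = TRUE),
                      sample(1:3, 30, replace = TRUE))
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("scoreProjection bundles aligned scores and respects id checks", {
  set.seed(36)
  X <- cbind(matrix(rnorm(60), 30, 2), matrix(0, 30, 2))
  es <- EmbeddingSet(X, ids = sprintf("i%02d", 1:30),
                     metadata = data.frame(grp = rep(c("a", "b"), 15)))
  proj <- new("ProjectionResult", ids = itemIds(es),
              coords = `dimnames<-`(X[, 1:2], list(itemIds(es), c("x", "y"))),
              params = projectorParams(), sourceHash = "h")
  sc <- scoreProjection(es, proj, "grp", k = 5, seed = 1)
  # projection = the informative feature plane: perfect preservation
  expect_equal(sc@knnPreservation, 1.0)
  expect_equal(sc@cpd, 1.0)
  expect_identical(sc@nScored, 30L)

  bad <- new("ProjectionResult", ids = c("nope", itemIds(es)[-1]),
             coords = proj@coords, params = projectorParams(),
             sourceHash = "h")
  expect_error(scoreProjection(es, bad, "grp"), "nope")
})

test_that("site-dominated embeddings separate and null embeddings do not", {
  strong <- genEmbeddings(syntheticConfig(delta = 10, sigma = 1,
                                          patientsPerSite = 6,
                                          tilesPerSlide = 5, seed = 40))
  proj <- projectEmbeddings(strong, projectorParams(seed = 1))
  sc <- scoreProjection(strong, proj, "site", seed = 1)
  expect_gt(sc@silhouette, 0.5)

  null <- genEmbeddings(syntheticConfig(delta = 0, sigma = 1,
                                        patientsPerSite = 6,
                                        tilesPerSlide = 5, seed = 41))
  projN <- projectEmbeddings(null, projectorParams(seed = 1))
  scN <- scoreProjection(null, projN, "site", seed = 1)
  expect_lt(abs(scN@ari), 0.1)
})
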