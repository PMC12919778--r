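#' @include projector.R
NULL

#' Mean silhouette width
#'
#' For each point, \eqn{s(i) = (b(i) - a(i)) / max(a(i), b(i))} with
#' \eqn{a(i)} the mean Euclidean distance to points of the same label
#' (self excluded) and \eqn{b(i)} the minimum over other labels of the
#' mean distance to that label's points. Points in singleton labels score
#' 0. Returns the mean over all points.
#'
#' @param points Numeric n x p matrix, n >= 2.
#' @param labels Length-n categorical labels with >= 2 distinct values.
#' @return Mean silhouette in [-1, 1].
#' @export
silhouetteScore <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  n <- nrow(points)
  if (n < 2L || length(labels) != n)
    flensError("need n >= 2 points with aligned labels")
  classes <- unique(labels)
  if (length(classes) < 2L) flensError("silhouette needs >= 2 distinct labels")
  D <- as.matrix(stats::dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- labels == labels[i]
    nSame <- sum(same) - 1L
    if (nSame == 0L) { s[i] <- 0; next }
    a <- sum(D[i, same]) / nSame          # D[i,i] = 0
    b <- min(vapply(setdiff(classes, labels[i]), function(cl)
      mean(D[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Adjusted Rand Index between two partitions
#'
#' Pair-counting agreement, corrected for chance:
#' \deqn{ARI = (\sum_{ij} \binom{n_{ij}}{2} - E) / (\frac{1}{2}(\sum_i \binom{a_i}{2} + \sum_j \binom{b_j}{2}) - E)}
#' with \eqn{E} the expected index under random partitions with the same
#' marginals. Invariant to label permutation. Two identical trivial
#' partitions score 1 by convention.
#'
#' @param x,y Length-n label vectors.
#' @return ARI in [-1, 1].
#' @export
adjustedRandIndex <- function(x, y) {
  x <- as.character(x); y <- as.character(y)
  if (length(x) != length(y)) flensError("partitions must have equal length")
  tab <- table(x, y)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  idx <- ch2(as.numeric(tab))
  a <- ch2(rowSums(tab)); b <- ch2(colSums(tab))
  nPairs <- ch2(length(x))
  expected <- a * b / nPairs
  maxIdx <- (a + b) / 2
  if (abs(maxIdx - expected) < 1e-12)
    return(if (abs(idx - expected) < 1e-12) 1 else 0)
  (idx - expected) / (maxIdx - expected)
}

#' K-means agreement with reference labels
#'
#' Runs Lloyd's algorithm with k equal to the number of distinct labels,
#' seeded greedy farthest-first initialisation (10 restarts, best total
#' within-cluster sum of squares wins, at most 300 iterations or centroid
#' shift below 1e-4), and returns the [adjustedRandIndex()] between the
#' resulting partition and the labels.
#'
#' @param points Numeric n x p matrix.
#' @param labels Length-n categorical reference labels, >= 2 distinct.
#' @param seed RNG seed for the restart start points.
#' @param restarts Number of restarts.
#' @return ARI in [-1, 1].
#' @export
kmeansARI <- function(points, labels, seed = 0L, restarts = 10L) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  k <- length(unique(labels))
  n <- nrow(points)
  if (k < 2L) flensError("need >= 2 distinct labels")
  if (k > n) flensError(sprintf("more labels (%d) than points (%d)", k, n))
  startIdx <- withSeed(seed, sample.int(n, restarts, replace = TRUE))
  best <- NULL; bestSS <- Inf
  for (r in seq_len(restarts)) {
    centers <- farthestFirst(points, k, startIdx[r])
    fit <- lloyd(points, centers)
    if (fit$ss < bestSS) { bestSS <- fit$ss; best <- fit$cluster }
  }
  adjustedRandIndex(best, labels)
}

## Greedy farthest-first traversal from a given start row.
farthestFirst <- function(points, k, start) {
  n <- nrow(points)
  chosen <- integer(k)
  chosen[1] <- start
  minD <- rowSums(sweep(points, 2L, points[start, ])^2)
  if (k > 1L) for (j in 2:k) {
    nxt <- which.max(minD)
    chosen[j] <- nxt
    minD <- pmin(minD, rowSums(sweep(points, 2L, points[nxt, ])^2))
  }
  points[chosen, , drop = FALSE]
}

lloyd <- function(points, centers, maxIter = 300L, shiftTol = 1e-4) {
  k <- nrow(centers)
  for (it in seq_len(maxIter)) {
    d2 <- outer(rowSums(points^2), rep(1, k)) -
      2 * points %*% t(centers) +
      outer(rep(1, nrow(points)), rowSums(centers^2))
    cl <- max.col(-d2, ties.method = "first")
    newCenters <- centers
    for (j in seq_len(k)) {
      idx <- cl == j
      if (any(idx)) newCenters[j, ] <- colMeans(points[idx, , drop = FALSE])
      ## empty cluster: keep the previous centroid
    }
    shift <- sqrt(max(rowSums((newCenters - centers)^2)))
    centers <- newCenters
    if (shift < shiftTol) break
  }
  d2 <- outer(rowSums(points^2), rep(1, k)) -
    2 * points %*% t(centers) +
    outer(rep(1, nrow(points)), rowSums(centers^2))
  cl <- max.col(-d2, ties.method = "first")
  ss <- sum(pmax(d2[cbind(seq_len(nrow(points)), cl)], 0))
  list(cluster = cl, ss = ss)
}

#' K-nearest-neighbour preservation between two spaces
#'
#' Mean over points of the overlap between the k nearest neighbours in the
#' high-dimensional space and in the low-dimensional one (Euclidean, self
#' excluded, distance ties broken by lower index), divided by k. Measures
#' how much local structure a projection retains.
#'
#' @param high Numeric n x d matrix.
#' @param low Numeric n x 2 (or n x p) matrix, rows aligned with
#'   \code{high}.
#' @param k Neighbourhood size, 1 <= k <= n - 1.
#' @return Preservation in [0, 1].
#' @export
knnPreservation <- function(high, low, k = 15L) {
  high <- as.matrix(high); low <- as.matrix(low)
  n <- nrow(high)
  if (nrow(low) != n) flensError("high and low must have the same rows")
  if (k < 1L || k > n - 1L)
    flensError(sprintf("k must be in [1, %d]", n - 1L))
  nnSets <- function(M) {
    D <- as.matrix(stats::dist(M))
    diag(D) <- Inf
    lapply(seq_len(n), function(i) order(D[i, ], seq_len(n))[seq_len(k)])
  }
  hi <- nnSets(high); lo <- nnSets(low)
  mean(vapply(seq_len(n), function(i)
    length(intersect(hi[[i]], lo[[i]])) / k, numeric(1)))
}

#' Correlation of pairwise distances (CPD)
#'
#' Spearman rank correlation (average ranks for ties) between the vectors
#' of all pairwise Euclidean distances in the high- and low-dimensional
#' spaces. Measures global structure preservation. For n above
#' \code{maxPoints} a seeded uniform subsample of \code{maxPoints} points
#' is scored instead (the full pair set grows quadratically).
#'
#' @param high,low Aligned numeric matrices, n >= 3 rows.
#' @param maxPoints Subsample cap (default 1000, about 500k pairs).
#' @param seed RNG seed for the subsample.
#' @return Spearman rho in [-1, 1].
#' @export
cpdScore <- function(high, low, maxPoints = 1000L, seed = 0L) {
  high <- as.matrix(high); low <- as.matrix(low)
  n <- nrow(high)
  if (nrow(low) != n) flensError("high and low must have the same rows")
  if (n < 3L) flensError("cpd needs n >= 3")
  if (n > maxPoints) {
    idx <- withSeed(seed, sample.int(n, maxPoints))
    high <- high[idx, , drop = FALSE]
    low <- low[idx, , drop = FALSE]
  }
  dh <- as.vector(stats::dist(high))
  dl <- as.vector(stats::dist(low))
  stats::cor(dh, dl, method = "spearman")
}

#' Score a projection against its source embeddings
#'
#' Bundles the four structure scores for one projection: silhouette and
#' k-means ARI of the label classes in the 2-D plane, k-nearest-neighbour
#' preservation and CPD between the original features and the plane. For
#' sets above \code{maxPoints} items, a seeded uniform subsample is scored
#' (pairwise distances are quadratic in n); the subsample size and seed are
#' recorded in the result.
#'
#' @param set The source \linkS4class{EmbeddingSet}.
#' @param projection A \linkS4class{ProjectionResult} whose ids are a
#'   subset of the set's.
#' @param variable A \linkS4class{VariableSpec} or variable name.
#' @param k Neighbourhood size for KNN preservation (default 15, the
#'   projector's neighbourhood default).
#' @param seed Subsample seed.
#' @param maxPoints Scoring subsample cap (default 5000).
#' @return A \linkS4class{StructureScores}.
#' @export
scoreProjection <- function(set, projection, variable, k = 15L, seed = 0L,
                            maxPoints = 5000L) {
  stopifnot(is(set, "EmbeddingSet"), is(projection, "ProjectionResult"))
  missing <- setdiff(projection@ids, itemIds(set))
  if (length(missing))
    flensError(sprintf("projection ids missing from set: %s",
                       paste(utils::head(missing, 5L), collapse = ", ")))
  sub <- subsetEmbeddings(set, projection@ids)
  high <- features(sub)
  low <- projection@coords
  labels <- variableLabels(sub, variable)
  n <- nrow(high)
  if (n > maxPoints) {
    idx <- withSeed(seed, sample.int(n, maxPoints))
    high <- high[idx, , drop = FALSE]
    low <- low[idx, , drop = FALSE]
    labels <- labels[idx]
    n <- maxPoints
  }
  new("StructureScores",
      silhouette = silhouetteScore(low, labels),
      ari = kmeansARI(low, labels, seed = seed),
      knnPreservation = knnPreservation(high, low, k = k),
      cpd = cpdScore(high, low, seed = seed),
      kUsed = as.integer(k), nScored = as.integer(n),
      subsampleSeed = as.integer(seed))
}
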