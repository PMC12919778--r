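#' @include EmbeddingSet.R
NULL

## Registry for the optional neighbor-embedding backend (e.g. a UMAP
## binding). The package itself ships only the deterministic linear
## fallback; anything stochastic and heavyweight is a runtime plug-in.
reducerEnv <- new.env(parent = emptyenv())

#' Register a neighbor-embedding reducer
#'
#' The reducer contract: a function
#' \code{function(features, nNeighbors, minDist, seed)} returning an
#' \code{n x 2} numeric matrix of finite coordinates. [projectEmbeddings()]
#' delegates to it for \code{method = "neighbor_embedding"}.
#'
#' @param fn The reducer function, or \code{NULL} to unregister.
#' @return The previously registered reducer, invisibly.
#' @export
setReducer <- function(fn) {
  old <- reducerEnv$reducer
  if (!is.null(fn)) stopifnot(is.function(fn))
  reducerEnv$reducer <- fn
  invisible(old)
}

#' @rdname ProjectorParams-class
#' @param method \code{"linear_fallback"} or \code{"neighbor_embedding"}.
#' @param nNeighbors Neighbourhood size for the neighbor-embedding backend.
#' @param minDist Minimum low-dimensional distance for the backend.
#' @param seed RNG seed.
#' @param sampleSizes Recommended projection sample sizes (one small for
#'   local patterns, one large for global ones).
#' @export
projectorParams <- function(method = c("linear_fallback", "neighbor_embedding"),
                            nNeighbors = 15L, minDist = 0.1, seed = 0L,
                            sampleSizes = c(10000L, 70000L)) {
  new("ProjectorParams", method = match.arg(method),
      nNeighbors = as.integer(nNeighbors), minDist = minDist,
      seed = as.integer(seed), sampleSizes = as.integer(sampleSizes))
}

#' Project embeddings to two dimensions
#'
#' \code{method = "neighbor_embedding"} delegates to the reducer registered
#' with [setReducer()], passing \code{nNeighbors}, \code{minDist} and
#' \code{seed} through. \code{method = "linear_fallback"} is built in and
#' fully deterministic: features are centred and projected onto the top
#' two principal directions, computed by an iterated power method with
#' deflation (tolerance 1e-10, at most 1000 iterations); the sign of each
#' direction is fixed so its largest-magnitude loading is positive. The
#' fallback ignores \code{nNeighbors} and \code{minDist} by design.
#'
#' @param set An \linkS4class{EmbeddingSet}; needs
#'   \code{n >= nNeighbors + 1} items for the neighbor embedding and
#'   \code{n >= 3} for the fallback.
#' @param params A \linkS4class{ProjectorParams}.
#' @return A \linkS4class{ProjectionResult}.
#' @export
projectEmbeddings <- function(set, params = projectorParams()) {
  stopifnot(is(set, "EmbeddingSet"), is(params, "ProjectorParams"))
  validObject(params)
  X <- features(set)
  n <- nrow(X)
  if (params@method == "neighbor_embedding") {
    if (n < params@nNeighbors + 1L)
      flensError(sprintf("need n >= nNeighbors + 1 (%d), got %d",
                         params@nNeighbors + 1L, n))
    fn <- reducerEnv$reducer
    if (is.null(fn))
      flensError(paste("no neighbor-embedding reducer registered;",
                       "call setReducer() or use method = 'linear_fallback'"))
    coords <- fn(X, params@nNeighbors, params@minDist, params@seed)
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 2L || any(!is.finite(coords)))
      flensError("reducer must return a finite n x 2 matrix")
  } else {
    if (n < 3L) flensError("linear_fallback needs n >= 3")
    coords <- pcaTop2(X, params@seed)
  }
  dimnames(coords) <- list(itemIds(set), c("x", "y"))
  new("ProjectionResult", ids = itemIds(set), coords = coords,
      params = params, sourceHash = featureHash(X))
}

## Top-2 principal coordinates via power iteration with deflation.
## Start vectors are drawn from the seed only (never from the data order),
## so the projection is permutation-equivariant in the rows.
pcaTop2 <- function(X, seed, tol = 1e-10, maxIter = 1000L) {
  Xc <- sweep(X, 2L, colMeans(X))
  d <- ncol(Xc)
  starts <- withSeed(seed, matrix(stats::rnorm(2L * d), d, 2L))

  fixSign <- function(v) {
    j <- which.max(abs(v))
    if (v[j] < 0) -v else v
  }
  v1 <- powerIter(Xc, starts[, 1], tol, maxIter)
  if (is.null(v1)) {                 # zero-variance data: all scores 0
    v1 <- numeric(d); v1[1] <- 1
  }
  v1 <- fixSign(v1)
  ## deflate: remove the first component's contribution, then iterate again;
  ## scores on the deflated matrix are exactly 0 for rank-1 data
  Xc2 <- Xc - (Xc %*% v1) %*% t(v1)
  v2 <- powerIter(Xc2, starts[, 2], tol, maxIter)
  if (is.null(v2)) {
    e <- numeric(d)
    e[which.min(abs(v1))] <- 1
    e <- e - sum(e * v1) * v1
    v2 <- e / sqrt(sum(e^2))
  }
  v2 <- fixSign(v2)
  cbind(Xc %*% v1, Xc2 %*% v2)
}

powerIter <- function(Xc, v0, tol, maxIter) {
  nrm <- sqrt(sum(v0^2))
  if (nrm < tol) return(NULL)
  v <- v0 / nrm
  denom <- max(1L, nrow(Xc) - 1L)
  for (i in seq_len(maxIter)) {
    w <- crossprod(Xc, Xc %*% v) / denom
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) return(NULL)
    w <- w / nw
    if (sum(w * v) < 0) w <- -w      # align sign before measuring the step
    if (sqrt(sum((w - v)^2)) < tol) return(as.numeric(w))
    v <- w
  }
  as.numeric(v)
}

featureHash <- function(X) {
  ## small order-sensitive digest of the feature content; base R only
  s <- c(dim(X), colSums(X), colSums(X^2), X[1, ], X[nrow(X), ])
  paste0("h", format(sum(s * seq_along(s)) %% 1e9, scientific = FALSE),
         "-", nrow(X), "x", ncol(X))
}

#' Sweep a parameter grid of projections
#'
#' One projection per (nNeighbors, minDist) pair, all computed from the
#' identical input sample, so panels are directly comparable. With the
#' linear fallback the parameters do not influence the coordinates; the
#' grid then documents that invariance.
#'
#' @param set An \linkS4class{EmbeddingSet}.
#' @param neighborValues,minDistValues Non-empty value vectors.
#' @param seed RNG seed shared by all grid cells.
#' @param method Projection method, as in [projectorParams()].
#' @return List of \linkS4class{ProjectionResult}, row-major over the
#'   (neighbor x minDist) grid.
#' @export
projectGrid <- function(set, neighborValues = c(15L), minDistValues = c(0.1),
                        seed = 0L, method = "linear_fallback") {
  if (!length(neighborValues) || !length(minDistValues))
    flensError("grid value lists must be non-empty")
  out <- vector("list", length(neighborValues) * length(minDistValues))
  i <- 0L
  for (nn in neighborValues) for (md in minDistValues) {
    i <- i + 1L
    out[[i]] <- projectEmbeddings(set, projectorParams(
      method = method, nNeighbors = nn, minDist = md, seed = seed))
  }
  out
}

#' Draw a projection sample
#'
#' Uniform sampling without replacement; with \code{stratifyBy}, per-class
#' counts are proportional to class frequencies, rounded by the
#' largest-remainder rule. \code{size = n} returns the whole set in
#' original order.
#'
#' @param set An \linkS4class{EmbeddingSet}.
#' @param size Sample size, at most \code{nItems(set)}.
#' @param stratifyBy Optional metadata variable name.
#' @param seed RNG seed.
#' @return An \linkS4class{EmbeddingSet} of \code{size} items.
#' @export
drawProjectionSample <- function(set, size, stratifyBy = NULL, seed = 0L) {
  stopifnot(is(set, "EmbeddingSet"))
  n <- nItems(set)
  if (size > n)
    flensError(sprintf("sample size %d exceeds set size %d", size, n))
  if (size == n) return(set)
  ids <- itemIds(set)
  keep <- if (is.null(stratifyBy)) {
    withSeed(seed, sample(ids, size))
  } else {
    labels <- itemMeta(set, stratifyBy)
    classes <- sort(unique(labels))
    counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
    quota <- largestRemainder(counts, size)
    withSeed(seed, {
      unlist(lapply(seq_along(classes), function(i)
        sample(ids[labels == classes[i]], quota[i])), use.names = FALSE)
    })
  }
  keep <- ids[ids %in% keep]   # original order
  subsetEmbeddings(set, keep)
}
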