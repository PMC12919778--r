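#' @include EmbeddingSet.R
NULL

#' @rdname ProbeConfig-class
#' @param epochs Training passes over the data (default 20).
#' @param batchSize Mini-batch size (default 256).
#' @param learningRate Adam step size (default 1e-3).
#' @param beta1,beta2 Adam moment decay rates.
#' @param nBootstrap Number of test-set bootstrap resamples (default 100).
#' @param ciLevel Confidence level for the percentile interval (default 0.95).
#' @param seed RNG seed covering initialisation, shuffling and bootstrap.
#' @export
probeConfig <- function(epochs = 20L, batchSize = 256L, learningRate = 1e-3,
                        beta1 = 0.9, beta2 = 0.999, nBootstrap = 100L,
                        ciLevel = 0.95, seed = 0L) {
  new("ProbeConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      beta1 = beta1, beta2 = beta2, nBootstrap = as.integer(nBootstrap),
      ciLevel = ciLevel, seed = as.integer(seed))
}

#' Train a linear probe
#'
#' Fits a single linear layer (d features to m class logits) on frozen
#' embeddings by minimising softmax cross-entropy with mini-batch Adam for
#' exactly \code{config@epochs} passes. Features are standardised
#' per dimension (mean 0, variance 1, statistics from this training split
#' only) before the linear layer; the standardisation travels with the
#' model. Training is a deterministic function of (data, config): weight
#' initialisation and the per-epoch shuffling order are drawn from one
#' seeded stream, so the same inputs and seed reproduce bitwise-identical
#' weights.
#'
#' @param train An \linkS4class{EmbeddingSet}.
#' @param variable A \linkS4class{VariableSpec} (or variable name) present
#'   in \code{train}, with at least two classes.
#' @param config A \linkS4class{ProbeConfig}.
#' @return A \linkS4class{ProbeModel}.
#' @seealso [evaluateProbe()], [probePredict()]
#' @export
trainProbe <- function(train, variable, config = probeConfig()) {
  stopifnot(is(train, "EmbeddingSet"), is(config, "ProbeConfig"))
  validObject(config)
  labels <- variableLabels(train, variable)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    flensError("need >=2 classes to train a probe")
  X <- features(train)
  n <- nrow(X); d <- ncol(X); m <- length(classes)
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  X <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  y <- match(labels, classes)

  ## one seeded stream for init + all epoch permutations
  rng <- withSeed(config@seed, {
    list(W = matrix(stats::rnorm(d * m, sd = 0.01), d, m),
         perms = lapply(seq_len(config@epochs), function(e) sample.int(n)))
  })
  W <- rng$W
  b <- numeric(m)
  mW <- matrix(0, d, m); vW <- matrix(0, d, m)
  mb <- numeric(m); vb <- numeric(m)
  lr <- config@learningRate; b1 <- config@beta1; b2 <- config@beta2
  eps <- 1e-8; t <- 0L
  for (epoch in seq_len(config@epochs)) {
    ord <- rng$perms[[epoch]]
    starts <- seq(1L, n, by = config@batchSize)
    for (s in starts) {
      idx <- ord[s:min(s + config@batchSize - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      nb <- length(idx)
      logits <- Xb %*% W + rep(b, each = nb)
      logits <- logits - apply(logits, 1L, max)
      P <- exp(logits)
      P <- P / rowSums(P)
      P[cbind(seq_len(nb), y[idx])] <- P[cbind(seq_len(nb), y[idx])] - 1
      gW <- crossprod(Xb, P) / nb
      gb <- colMeans(P)
      t <- t + 1L
      mW <- b1 * mW + (1 - b1) * gW; vW <- b2 * vW + (1 - b2) * gW^2
      mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
      c1 <- 1 - b1^t; c2 <- 1 - b2^t
      W <- W - lr * (mW / c1) / (sqrt(vW / c2) + eps)
      b <- b - lr * (mb / c1) / (sqrt(vb / c2) + eps)
    }
  }
  new("ProbeModel", weights = W, bias = b, classLabels = classes,
      center = center, scale = scale,
      provenance = list(epochs = config@epochs, batchSize = config@batchSize,
                        learningRate = lr, seed = config@seed,
                        standardized = TRUE, nTrain = n,
                        variable = if (is(variable, "VariableSpec"))
                          variable@name else as.character(variable)))
}

#' Predict classes with a trained probe
#'
#' Applies the model's standardisation and affine map; the prediction is
#' the argmax logit, ties broken toward the lowest class index.
#'
#' @param model A \linkS4class{ProbeModel}.
#' @param set An \linkS4class{EmbeddingSet} with matching feature dimension.
#' @return Character vector of predicted class labels, one per item.
#' @export
probePredict <- function(model, set) {
  stopifnot(is(model, "ProbeModel"), is(set, "EmbeddingSet"))
  X <- features(set)
  if (ncol(X) != nrow(model@weights))
    flensError(sprintf("feature dimension %d does not match model (%d)",
                       ncol(X), nrow(model@weights)))
  X <- sweep(sweep(X, 2L, model@center), 2L, model@scale, "/")
  scores <- X %*% model@weights + rep(model@bias, each = nrow(X))
  model@classLabels[max.col(scores, ties.method = "first")]
}

#' Evaluate a probe on a held-out test set
#'
#' Computes accuracy once on the full test set, then bootstraps the test
#' set (sampling items with replacement \code{config@nBootstrap} times) to
#' obtain a percentile confidence interval for accuracy and a per-replicate
#' Cohen's kappa, reported as the mean over replicates in which kappa is
#' defined.
#'
#' @param model A \linkS4class{ProbeModel}.
#' @param test An \linkS4class{EmbeddingSet}; its classes for
#'   \code{variable} must be a subset of the model's.
#' @param variable A \linkS4class{VariableSpec} or variable name.
#' @param config A \linkS4class{ProbeConfig} (bootstrap count, CI level,
#'   seed).
#' @return A \linkS4class{ProbeResult}.
#' @export
evaluateProbe <- function(model, test, variable, config = probeConfig()) {
  stopifnot(is(model, "ProbeModel"), is(test, "EmbeddingSet"),
            is(config, "ProbeConfig"))
  if (nItems(test) == 0L) flensError("empty test set")
  truth <- variableLabels(test, variable)
  extra <- setdiff(unique(truth), model@classLabels)
  if (length(extra))
    flensError(sprintf("test classes not known to the model: %s",
                       paste(extra, collapse = ", ")))
  pred <- probePredict(model, test)
  n <- length(truth)
  lv <- model@classLabels
  confusion <- unclass(table(factor(truth, levels = lv),
                             factor(pred, levels = lv)))
  confusion <- matrix(as.numeric(confusion), length(lv), length(lv),
                      dimnames = list(true = lv, predicted = lv))
  accuracy <- sum(diag(confusion)) / n

  correct <- pred == truth
  boot <- withSeed(config@seed, {
    replicate(config@nBootstrap, sample.int(n, n, replace = TRUE),
              simplify = FALSE)
  })
  accB <- vapply(boot, function(idx) mean(correct[idx]), numeric(1))
  kapB <- vapply(boot, function(idx) {
    cm <- unclass(table(factor(truth[idx], levels = lv),
                        factor(pred[idx], levels = lv)))
    cohenKappa(cm)
  }, numeric(1))
  a <- (1 - config@ciLevel) / 2
  ci <- unname(stats::quantile(accB, c(a, 1 - a)))
  kappaMean <- if (all(is.na(kapB))) NA_real_ else mean(kapB, na.rm = TRUE)

  rowTot <- rowSums(confusion)
  perClass <- ifelse(rowTot > 0, diag(confusion) / rowTot, NA_real_)
  names(perClass) <- lv
  new("ProbeResult", accuracy = accuracy, ciLow = ci[1], ciHigh = ci[2],
      kappaMean = kappaMean, perClassAccuracy = perClass,
      confusion = confusion, nTrain = as.integer(model@provenance$nTrain %||% NA),
      nTest = as.integer(n), nClasses = length(lv), seed = config@seed,
      provenance = c(model@provenance,
                     list(nBootstrap = config@nBootstrap,
                          ciLevel = config@ciLevel,
                          bootAccuracies = accB)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement
#' \eqn{p_o = trace / total} and chance agreement
#' \eqn{p_e = \sum_k row_k \cdot col_k / total^2}. Returns \code{NA} (the
#' undefined sentinel) when chance agreement equals 1, as for a one-cell
#' matrix.
#'
#' @param confusion Square numeric matrix of non-negative counts
#'   (rows = true, columns = predicted), total > 0.
#' @return Numeric kappa in [-1, 1], or \code{NA} when undefined.
#' @examples
#' cohenKappa(matrix(c(10, 0, 0, 10), 2))  # 1
#' cohenKappa(matrix(c(20, 10, 5, 15), 2)) # 0.4
#' @export
cohenKappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    flensError("confusion matrix must be square")
  if (any(confusion < 0)) flensError("confusion entries must be non-negative")
  total <- sum(confusion)
  if (total == 0) flensError("confusion matrix is all zero")
  po <- sum(diag(confusion)) / total
  pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (abs(1 - pe) < 1e-15) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Probe accuracy as a function of training-set size
#'
#' Re-runs the probe on stratified subsamples of the training data at each
#' requested fraction, keeping the test set fixed, and reports the mean and
#' standard deviation of the held-out accuracy over \code{repeats}
#' independent draws. At small fractions (at most \code{smallThreshold},
#' default 0.25) the epoch count is raised to \code{epochsSmall} (default
#' 60) to compensate for the reduced data.
#'
#' @param train,test \linkS4class{EmbeddingSet}s; \code{test} is reused
#'   unchanged across every run.
#' @param variable A \linkS4class{VariableSpec} or variable name.
#' @param fractions Sorted vector of fractions in (0, 1]. A fraction that
#'   would leave any class empty is an error.
#' @param repeats Independent subsample draws per fraction.
#' @param config Base \linkS4class{ProbeConfig}.
#' @param epochsSmall,smallThreshold Epoch compensation rule.
#' @return A data.frame with columns \code{fraction}, \code{meanAccuracy},
#'   \code{sdAccuracy}, \code{nTrain}; per-run accuracies in the
#'   \code{"runs"} attribute.
#' @export
subsampleExperiment <- function(train, test, variable, fractions,
                                repeats = 5L, config = probeConfig(),
                                epochsSmall = 60L, smallThreshold = 0.25) {
  stopifnot(all(fractions > 0), all(fractions <= 1),
            !is.unsorted(fractions), repeats >= 1L)
  labels <- variableLabels(train, variable)
  ids <- itemIds(train)
  classCounts <- table(labels)
  seeds <- matrix(subSeeds(config@seed, length(fractions) * repeats),
                  nrow = length(fractions))
  runs <- vector("list", length(fractions))
  out <- data.frame(fraction = fractions, meanAccuracy = NA_real_,
                    sdAccuracy = NA_real_, nTrain = NA_integer_)
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    take <- round(f * as.numeric(classCounts))
    if (any(take < 1L)) {
      empty <- names(classCounts)[which(take < 1L)[1]]
      flensError(sprintf("fraction %g leaves class '%s' empty", f, empty))
    }
    cfg <- config
    if (f <= smallThreshold) cfg@epochs <- as.integer(epochsSmall)
    acc <- numeric(repeats)
    for (r in seq_len(repeats)) {
      sub <- if (f == 1) ids else withSeed(seeds[i, r], {
        unlist(lapply(names(classCounts), function(cl) {
          pool <- ids[labels == cl]
          sample(pool, take[match(cl, names(classCounts))])
        }), use.names = FALSE)
      })
      cfg@seed <- seeds[i, r]
      model <- trainProbe(subsetEmbeddings(train, sub), variable, cfg)
      acc[r] <- evaluateProbe(model, test, variable, cfg)@accuracy
    }
    runs[[i]] <- acc
    out$meanAccuracy[i] <- mean(acc)
    out$sdAccuracy[i] <- if (repeats > 1L) stats::sd(acc) else 0
    out$nTrain[i] <- as.integer(sum(take))
  }
  attr(out, "runs") <- runs
  out
}
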