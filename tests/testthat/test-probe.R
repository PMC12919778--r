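test_that("cohenKappa matches the direct formula on fixed confusion matrices", {
  expect_equal(cohenKappa(matrix(c(10, 0, 0, 10), 2)), 1.0)
  # p_o = 0.7, p_e = (25*30 + 25*20) / 50^2 = 0.5 -> kappa 0.4
  expect_equal(cohenKappa(matrix(c(20, 10, 5, 15), 2)), 0.4)
  # constant predictor: p_o = p_e = 0.6 -> 0
  expect_equal(cohenKappa(matrix(c(15, 10, 0, 0), 2)), 0.0)
  # one-cell matrix: chance agreement 1 -> undefined sentinel
  expect_true(is.na(cohenKappa(matrix(c(7, 0, 0, 0), 2))))
  expect_error(cohenKappa(matrix(0, 2, 2)), "all zero")
})

test_that("kappa is invariant under simultaneous row/column permutation", {
  set.seed(5)
  for (rep in 1:20) {
    m <- matrix(rpois(16, 5), 4)
    p <- sample(4)
    expect_equal(cohenKappa(m[p, p]), cohenKappa(m))
  }
})

test_that("well-separated two-class data is learned to near-Bayes accuracy", {
  set.seed(10)
  mk <- function(n) {
    x <- matrix(c(rnorm(n / 2, -5, 0.1), rnorm(n / 2, 5, 0.1)), ncol = 1)
    EmbeddingSet(x, ids = sprintf("i%03d_%d", seq_len(n), rbinom(n, 1e6, .5)),
                 metadata = data.frame(y = rep(c("neg", "pos"), each = n / 2)))
  }
  cfg <- probeConfig(seed = 1)
  model <- trainProbe(mk(200), "y", cfg)
  fresh <- mk(200)
  acc <- mean(probePredict(model, fresh) == itemMeta(fresh, "y"))
  expect_gte(acc, 0.99)
})

test_that("a probe on pure noise stays near chance", {
  set.seed(11)
  feat <- matrix(rnorm(400 * 4), 400, 4)
  es <- EmbeddingSet(feat, ids = sprintf("i%03d", 1:400),
                     metadata = data.frame(y = rep(c("a", "b"), 200)))
  cfg <- probeConfig(seed = 2)
  model <- trainProbe(subsetEmbeddings(es, itemIds(es)[1:200]), "y", cfg)
  held <- subsetEmbeddings(es, itemIds(es)[201:400])
  acc <- mean(probePredict(model, held) == itemMeta(held, "y"))
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
})

test_that("training is bitwise deterministic given data and seed", {
  es <- genEmbeddings(syntheticConfig(patientsPerSite = 4, tilesPerSlide = 5,
                                      delta = 2, seed = 3))
  cfg <- probeConfig(epochs = 3, seed = 7)
  m1 <- trainProbe(es, "site", cfg)
  m2 <- trainProbe(es, "site", cfg)
  expect_identical(m1@weights, m2@weights)
  expect_identical(m1@bias, m2@bias)
})

test_that("training rejects degenerate variables", {
  es <- EmbeddingSet(matrix(rnorm(20), 10), ids = letters[1:10],
                     metadata = data.frame(y = rep("only", 10)))
  expect_error(trainProbe(es, "y"), ">=2 classes")
  expect_error(trainProbe(es, "missing_var"), "missing_var")
})

test_that("evaluateProbe handles the perfect and constant-predictor cases", {
  # features encode the class exactly; model is hand-built so predictions
  # are fully controlled
  perfect <- new("ProbeModel", weights = matrix(c(1, -1), 1), bias = c(0, 0),
                 classLabels = c("a", "b"), center = 0, scale = 1,
                 provenance = list(nTrain = 0L))
  n <- 50
  x <- matrix(rep(c(1, -1), each = n / 2), ncol = 1)
  es <- EmbeddingSet(x, ids = sprintf("i%02d", 1:n),
                     metadata = data.frame(y = rep(c("a", "b"), each = n / 2)))
  r <- evaluateProbe(perfect, es, "y", probeConfig(seed = 1))
  expect_equal(r@accuracy, 1.0)
  expect_equal(c(r@ciLow, r@ciHigh), c(1, 1))
  expect_equal(r@kappaMean, 1.0)
  expect_equal(sum(r@confusion), r@nTest)

  # constant predictor: kappa is exactly 0 in every bootstrap replicate
  constant <- new("ProbeModel", weights = matrix(c(1, 0), 1), bias = c(1, 0),
                  classLabels = c("a", "b"), center = 0, scale = 1,
                  provenance = list(nTrain = 0L))
  xz <- matrix(0, n, 1)
  es2 <- EmbeddingSet(xz, ids = sprintf("i%02d", 1:n),
                      metadata = data.frame(y = rep(c("a", "b"), each = n / 2)))
  r2 <- evaluateProbe(constant, es2, "y", probeConfig(seed = 2))
  expect_equal(r2@kappaMean, 0.0)
  expect_equal(r2@accuracy, 0.5)

  expect_error(evaluateProbe(perfect,
                             subsetEmbeddings(es, character(0)), "y"),
               "empty")
})

test_that("reported accuracy equals trace(confusion)/nTest exactly", {
  es <- genEmbeddings(syntheticConfig(patientsPerSite = 4, tilesPerSlide = 5,
                                      delta = 3, seed = 9))
  cfg <- probeConfig(epochs = 5, seed = 4)
  model <- trainProbe(es, "site", cfg)
  r <- evaluateProbe(model, es, "site", cfg)
  expect_identical(r@accuracy, sum(diag(r@confusion)) / r@nTest)
  expect_true(all(r@perClassAccuracy >= 0 & r@perClassAccuracy <= 1,
                  na.rm = TRUE))
})

test_that("subsampleExperiment honors its contract", {
  es <- genEmbeddings(syntheticConfig(patientsPerSite = 6, tilesPerSlide = 5,
                                      delta = 4, seed = 12))
  sp <- patientDisjointSplit(es, seed = 1)
  tr <- splitItems(es, sp, "train")
  te <- splitItems(es, sp, "test")
  cfg <- probeConfig(epochs = 5, nBootstrap = 10, seed = 6)

  # fraction 1.0, one repeat: equals a plain train+evaluate run at the
  # subsample's derived seed
  tab <- subsampleExperiment(tr, te, "site", fractions = 1.0, repeats = 1,
                             config = cfg)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$nTrain, nItems(tr))
  seedUsed <- attr(tab, "runs")
  cfg2 <- cfg
  cfg2@seed <- featurelens:::subSeeds(cfg@seed, 1L)[1]
  direct <- evaluateProbe(trainProbe(tr, "site", cfg2), te, "site", cfg2)
  expect_equal(tab$meanAccuracy, direct@accuracy)

  # a fraction that empties a class errors
  tiny <- EmbeddingSet(matrix(rnorm(200 * 2), 200), ids = sprintf("t%03d", 1:200),
                       metadata = data.frame(y = rep(letters[1:5], 40)))
  expect_error(subsampleExperiment(tiny, tiny, "y", fractions = 0.001,
                                   repeats = 1), "empty")
})
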