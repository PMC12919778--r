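test_that("tileGrid tessellates with stride round(side * (1 - overlap))", {
  g1 <- tileGrid(1024, 1024, 1024, 0.25)
  expect_identical(nrow(g1@origins), 1L)
  expect_identical(unname(g1@origins[1, ]), c(0L, 0L))

  # 1792 = 1024 + 768: two tiles along x
  g2 <- tileGrid(1792, 1024, 1024, 0.25)
  expect_identical(unname(g2@origins), cbind(c(0L, 768L), c(0L, 0L)))

  expect_identical(nrow(tileGrid(1000, 1000, 1024, 0.25)@origins), 0L)

  # origin count formula whenever a tile fits
  for (w in c(1024, 2000, 3000)) for (h in c(1024, 1500)) {
    g <- tileGrid(w, h, 1024, 0.25)
    expected <- (floor((w - 1024) / 768) + 1) * (floor((h - 1024) / 768) + 1)
    expect_identical(nrow(g@origins), as.integer(expected))
    expect_true(all(g@origins[, 1] + 1024 <= w))
    expect_true(all(g@origins[, 2] + 1024 <= h))
  }
})

test_that("whitespace fraction counts pixels with all channels >= 220/255", {
  expect_equal(whitespaceFraction(array(1, c(4, 4, 3))), 1.0)
  expect_equal(whitespaceFraction(array(0, c(4, 4, 3))), 0.0)

  # constructed 10x10 tile with exactly 84 white pixels
  g <- genTiles(0.84, side = 10, seed = 1)
  expect_equal(whitespaceFraction(g$tiles[[1]]), 0.84)

  # a pixel white in only two channels is not whitespace
  img <- array(1, c(2, 2, 3)); img[1, 1, 3] <- 0.5
  expect_equal(whitespaceFraction(img), 0.75)
})

test_that("filterWhitespace removes strictly above the threshold", {
  g <- genTiles(c(0, 0.85, 1), side = 20, seed = 2)
  expect_identical(filterWhitespace(g$tiles), c(1L, 2L))   # 0.85 kept
  expect_identical(filterWhitespace(g$tiles, threshold = 0.5), 1L)
  g86 <- genTiles(0.86, side = 10, seed = 3)
  expect_identical(filterWhitespace(g86$tiles), integer(0))
})

test_that("topNGroups ranks the printed site tile counts correctly", {
  counts <- c("22" = 19499, "39" = 32686, "60" = 19300,
              "66" = 25694, "85" = 49355)
  expect_identical(topNGroups(counts, 5), c("85", "39", "66", "22", "60"))
  expect_identical(topNGroups(counts, 99), c("85", "39", "66", "22", "60"))
  expect_identical(topNGroups(c(A = 10, B = 10), 1), "A")   # tie: id ascending
  expect_error(topNGroups(numeric(0), 1), "empty")
})

test_that("balanceByCovariate equalises cells and drops unshared levels", {
  mkSet <- function(groups, stages) {
    n <- length(groups)
    EmbeddingSet(matrix(rnorm(n * 2), n), ids = sprintf("i%03d", seq_len(n)),
                 metadata = data.frame(site = groups, stage = stages))
  }
  # cells (g1,s1):5 (g1,s2):9 (g2,s1):7 (g2,s2):5 -> every cell at 5
  set <- mkSet(rep(c("g1", "g2"), c(14, 12)),
               c(rep("s1", 5), rep("s2", 9), rep("s1", 7), rep("s2", 5)))
  bal <- balanceByCovariate(set, "site", "stage", seed = 1)
  tab <- table(itemMeta(bal, "site"), itemMeta(bal, "stage"))
  expect_true(all(tab == 5))

  # already equal: counts unchanged
  eq <- mkSet(rep(c("g1", "g2"), each = 20), rep(c("s1", "s2"), 20))
  balEq <- balanceByCovariate(eq, "site", "stage", seed = 1)
  expect_true(all(table(itemMeta(balEq, "site"), itemMeta(balEq, "stage")) == 10))

  # stage IV present only in one group is dropped before balancing
  set4 <- mkSet(rep(c("g1", "g2"), c(10, 12)),
                c(rep(c("I", "II"), 5), rep(c("I", "II"), 5), "IV", "IV"))
  bal4 <- balanceByCovariate(set4, "site", "stage", seed = 2)
  expect_false("IV" %in% itemMeta(bal4, "stage"))
  expect_true(all(table(itemMeta(bal4, "site"), itemMeta(bal4, "stage")) == 5))

  # identical contingency rows for all groups on random instances
  set.seed(44)
  for (rep in 1:5) {
    n <- 120
    rnd <- mkSet(sample(c("a", "b", "c"), n, TRUE),
                 sample(c("I", "II", "III"), n, TRUE))
    balR <- balanceByCovariate(rnd, "site", "stage", seed = rep)
    tabR <- table(itemMeta(balR, "site"), itemMeta(balR, "stage"))
    expect_identical(length(unique(as.vector(tabR))), 1L)
  }

  # disjoint covariate support is an error naming a group
  disj <- mkSet(rep(c("g1", "g2"), each = 4),
                c(rep("I", 4), rep("II", 4)))
  expect_error(balanceByCovariate(disj, "site", "stage"), "g1|g2")
})

test_that("patientDisjointSplit keeps units intact near target fractions", {
  mkHier <- function(nPat, tilesPer) {
    n <- nPat * tilesPer
    EmbeddingSet(matrix(rnorm(n * 2), n), ids = sprintf("i%04d", seq_len(n)),
                 metadata = data.frame(
                   patient = rep(sprintf("p%02d", seq_len(nPat)), each = tilesPer)))
  }
  # 10 equal units at (0.7, 0.15, 0.15): greedy yields 7 train units and
  # item fractions within one unit share of the targets
  es <- mkHier(10, 8)
  sp <- patientDisjointSplit(es, seed = 1)
  tab <- table(sp@assignments) / nItems(es)
  expect_equal(unname(tab["train"]), 0.7, tolerance = 0.11)
  expect_true(all(c("train", "validation", "test") %in% names(tab)))

  # unit disjointness across random instances
  set.seed(45)
  for (rep in 1:20) {
    nPat <- sample(5:20, 1)
    es <- mkHier(nPat, sample(2:6, 1))
    sp <- patientDisjointSplit(es, seed = rep)
    pats <- itemMeta(es, "patient")
    bySplit <- split(pats, sp@assignments[itemIds(es)])
    sets <- lapply(bySplit, unique)
    for (i in seq_along(sets)) for (j in seq_len(i - 1L))
      expect_length(intersect(sets[[i]], sets[[j]]), 0)
    # deviation bounded by the largest unit's share
    share <- max(table(pats)) / nItems(es)
    frac <- sapply(c("train", "validation", "test"), function(s)
      sum(sp@assignments == s) / nItems(es))
    expect_true(all(abs(frac - c(0.7, 0.15, 0.15)) <= share + 1e-9))
  }

  expect_error(patientDisjointSplit(mkHier(2, 3)), "at least 3")
  expect_error(patientDisjointSplit(mkHier(5, 2), fractions = c(0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("seeded sampling operations are reproducible", {
  es <- genEmbeddings(syntheticConfig(patientsPerSite = 12, tilesPerSlide = 4,
                                      seed = 5))
  expect_identical(patientDisjointSplit(es, seed = 9)@assignments,
                   patientDisjointSplit(es, seed = 9)@assignments)
  expect_identical(itemIds(drawProjectionSample(es, 50, seed = 9)),
                   itemIds(drawProjectionSample(es, 50, seed = 9)))
  expect_identical(itemIds(balanceByCovariate(es, "site", "class", seed = 9)),
                   itemIds(balanceByCovariate(es, "site", "class", seed = 9)))
})
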