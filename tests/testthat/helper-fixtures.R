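# Shared fixtures and independent brute-force oracles.
# Oracles deliberately avoid the code paths of the implementation:
# distances via explicit loops, neighbours via pair sorting, ARI via literal
# pair counting, Spearman via hand-computed average ranks + Pearson.

makeSet <- function(n = 6, d = 4, seed = 1, meta = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  EmbeddingSet(X, ids = sprintf("item%02d", seq_len(n)), metadata = meta)
}

pairDist <- function(M) {
  n <- nrow(M)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((M[i, ] - M[j, ])^2))
  D
}

oracleSilhouette <- function(points, labels) {
  D <- pairDist(as.matrix(points))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    sameIdx <- setdiff(which(labels == own), i)
    if (!length(sameIdx)) { s[i] <- 0; next }
    a <- mean(D[i, sameIdx])
    b <- Inf
    for (cl in setdiff(unique(labels), own))
      b <- min(b, mean(D[i, labels == cl]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# ARI by literal pair counting: classify every unordered pair as together in
# both partitions (n11), in one only (n10/n01), or in neither (n00).
oracleARI <- function(x, y) {
  n <- length(x)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- x[i] == x[j]; sy <- y[i] == y[j]
    if (sx && sy) n11 <- n11 + 1
    else if (sx) n10 <- n10 + 1
    else if (sy) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  a <- n11 + n10; b <- n11 + n01; tot <- n11 + n10 + n01 + n00
  expected <- a * b / tot
  maxIdx <- (a + b) / 2
  if (abs(maxIdx - expected) < 1e-12) return(1)
  (n11 - expected) / (maxIdx - expected)
}

oracleKNN <- function(high, low, k) {
  Dh <- pairDist(as.matrix(high)); Dl <- pairDist(as.matrix(low))
  n <- nrow(Dh)
  nbr <- function(D, i) {
    o <- setdiff(seq_len(n), i)
    o[order(D[i, o], o)][seq_len(k)]
  }
  mean(sapply(seq_len(n), function(i)
    length(intersect(nbr(Dh, i), nbr(Dl, i))) / k))
}

avgRank <- function(v) {
  r <- numeric(length(v))
  for (i in seq_along(v))
    r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  r
}

oracleCPD <- function(high, low) {
  Dh <- pairDist(as.matrix(high)); Dl <- pairDist(as.matrix(low))
  dh <- Dh[upper.tri(Dh)]; dl <- Dl[upper.tri(Dl)]
  rh <- avgRank(dh); rl <- avgRank(dl)
  sum((rh - mean(rh)) * (rl - mean(rl))) /
    sqrt(sum((rh - mean(rh))^2) * sum((rl - mean(rl))^2))
}
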