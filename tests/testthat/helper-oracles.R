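# Independent oracles used across test files.

# Numerator relationships by the textbook tabular recursion, written over
# id strings (independent of the package's compiled implementation).
tabularOracle <- function(rec) {
  n <- nrow(rec)
  A <- matrix(0, n, n, dimnames = list(rec$id, rec$id))
  for (i in seq_len(n)) {
    s <- rec$sire[i]; d <- rec$dam[i]
    for (j in seq_len(i - 1)) {
      a <- 0
      if (!is.na(s)) a <- a + 0.5 * A[rec$id[j], s]
      if (!is.na(d)) a <- a + 0.5 * A[rec$id[j], d]
      A[i, j] <- A[j, i] <- a
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

# Per-SNP generalized least squares with an explicit V, via the full
# normal equations on [X w].
glsOracle <- function(y, X, V, w) {
  Vi <- solve(V)
  Xa <- cbind(X, w)
  C <- solve(t(Xa) %*% Vi %*% Xa)
  b <- C %*% (t(Xa) %*% Vi %*% y)
  k <- ncol(Xa)
  c(effect = b[k], se = sqrt(C[k, k]))
}

# Random valid pedigree: each animal draws parents among earlier animals
# (or stays a founder), sexes enforced.
randomPedigree <- function(n, pFounder = 0.25) {
  id <- sprintf("P%03d", seq_len(n))
  sex <- rep_len(c("male", "female"), n)
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > 4 && stats::runif(1) > pFounder) {
      males <- which(sex[seq_len(i - 1)] == "male")
      females <- which(sex[seq_len(i - 1)] == "female")
      if (length(males)) sire[i] <- id[sample(males, 1)]
      if (length(females)) dam[i] <- id[sample(females, 1)]
    }
  }
  asPedigree(data.frame(id = id, sire = sire, dam = dam,
                        birth = seq_len(n), sex = sex, genotyped = TRUE))
}

# Discrete-generation random-mating population of constant census size N
# (the idealized Wright-Fisher-like pedigree used for drift validation).
wfPedigree <- function(N, gens, seed) {
  cfg <- simConfig(nLines = 1, years = 2001:(2000 + gens), preYears = 1,
                   nSiresPerYear = N / 2, nDamsPerYear = N / 2,
                   litterSize = 2, parentAgeProbs = c("1" = 1),
                   nMarkers = 10, nQtl = 2, selection = "random",
                   matingDesign = "random_pairs", genotypedFraction = 1)
  simulatePopulation(cfg, seed = seed)$pedigree
}

# Hardy-Weinberg genotype matrix with named dims.
hwGenotypes <- function(n, m, pRange = c(0.1, 0.9)) {
  p <- stats::runif(m, pRange[1], pRange[2])
  matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n,
         dimnames = list(sprintf("a%04d", seq_len(n)),
                         sprintf("s%04d", seq_len(m))))
}

# Polygenic response y = g + e with g ~ N(0, h2 * G), Var(y) = 1.
polygenicY <- function(G, h2) {
  n <- nrow(G)
  eg <- eigen(G, symmetric = TRUE)
  g <- as.numeric(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * stats::rnorm(n)))
  g * sqrt(h2) + stats::rnorm(n, 0, sqrt(1 - h2))
}
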