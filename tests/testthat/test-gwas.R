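test_that("VanRaden GRM matches the hand-computed example and invariants", {
  M2 <- matrix(c(0, 2, 2, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("x", "y"), c("m1", "m2")))
  grm <- computeGrm(GenotypeData(M2))
  expect_equal(grm@denom, 1)
  expect_equal(unname(grmMatrix(grm)), matrix(c(2, -2, -2, 2), 2))

  set.seed(31)
  M <- hwGenotypes(50, 80)
  g <- computeGrm(GenotypeData(M))
  expect_lt(abs(sum(grmMatrix(g))) / sum(abs(grmMatrix(g))), 1e-10)
  expect_true(isSymmetric(grmMatrix(g)))

  # duplicating every marker leaves G unchanged
  Mdup <- cbind(M, M)
  colnames(Mdup) <- sprintf("d%04d", seq_len(ncol(Mdup)))
  expect_equal(grmMatrix(computeGrm(GenotypeData(Mdup))), grmMatrix(g),
               tolerance = 1e-12, ignore_attr = TRUE)

  Mono <- cbind(M, fixed = rep(2, 50))
  expect_error(computeGrm(GenotypeData(Mono)), "monomorphic")
})

test_that("design assembly drops incomplete records and degenerate traits", {
  ph <- data.frame(animal = sprintf("a%d", 1:6),
                   y = c(1, 2, NA, 4, 5, 6),
                   sex = c("m", "f", "m", NA, "m", "f"),
                   pen = c("p1", "p1", "p2", "p2", "p2", "p1"))
  des <- gwasDesign(ph, "y", fixed = "sex", random = "pen")
  expect_equal(length(des$y), 4)        # two incomplete rows dropped
  expect_equal(ncol(des$X), 2)          # intercept + sex
  expect_equal(dim(des$Z$pen), c(4, 2))
  expect_error(gwasDesign(data.frame(animal = "a", y = 0), "y"),
               "zero variance")
})

test_that("REML recovers simulated heritability (marker-based GRM)", {
  est <- sapply(1:5, function(s) {
    set.seed(100 + s)
    M <- hwGenotypes(800, 400)
    grm <- computeGrm(GenotypeData(M))
    y <- polygenicY(grmMatrix(grm), 0.35)
    des <- gwasDesign(data.frame(animal = rownames(M), y = y), "y")
    heritability(remlNull(des, grm))
  })
  expect_lt(abs(median(est) - 0.35), 0.05)
})

test_that("REML with an extra random factor matches the eigen path when
           that factor is absent from the data-generating model", {
  set.seed(77)
  M <- hwGenotypes(250, 200)
  grm <- computeGrm(GenotypeData(M))
  y <- polygenicY(grmMatrix(grm), 0.4)
  ph <- data.frame(animal = rownames(M), y = y,
                   batch = rep(sprintf("b%d", 1:5), each = 50))
  des0 <- gwasDesign(ph, "y")
  des1 <- gwasDesign(ph, "y", random = "batch")
  vc0 <- remlNull(des0, grm)
  vc1 <- remlNull(des1, grm)
  expect_equal(vc1@sigmaA, vc0@sigmaA, tolerance = 0.05)
  expect_lt(vc1@extra[["batch"]], 0.05)
  expect_equal(vc1@logLik, vc0@logLik, tolerance = 1e-3)
})

test_that("scan equals the explicit-V GLS oracle, both model paths", {
  set.seed(55)
  n <- 150
  M <- hwGenotypes(n, 40)
  g <- GenotypeData(M)
  grm <- computeGrm(g)
  y <- polygenicY(grmMatrix(grm), 0.3)
  ph <- data.frame(animal = rownames(M), y = y,
                   sex = rep_len(c("m", "f"), n),
                   litter = rep(sprintf("L%02d", 1:25), each = 6))
  for (ran in list(character(0), "litter")) {
    des <- gwasDesign(ph, "y", fixed = "sex", random = ran)
    vc <- remlNull(des, grm)
    res <- snpScan(des, grm, vc, g)
    V <- vc@sigmaA * grmMatrix(grm)[des$animal, des$animal] +
      diag(vc@sigmaE, n)
    if (length(ran)) V <- V + vc@extra[[ran]] * tcrossprod(des$Z[[ran]])
    for (j in sample(40, 12)) {
      o <- glsOracle(des$y, des$X, V, M[des$animal, j])
      expect_equal(res$effect[j], unname(o["effect"]), tolerance = 1e-8)
      expect_equal(res$se[j], unname(o["se"]), tolerance = 1e-8)
    }
  }
})

test_that("scan degenerates to OLS without genetic variance and is
           invariant to animal permutation", {
  set.seed(66)
  n <- 120
  M <- hwGenotypes(n, 30)
  g <- GenotypeData(M)
  grm <- computeGrm(g)
  y <- stats::rnorm(n) + 0.3 * M[, 5]
  ph <- data.frame(animal = rownames(M), y = y,
                   sex = rep_len(c("m", "f"), n))
  des <- gwasDesign(ph, "y", fixed = "sex")
  vc0 <- methods::new("VarianceComponents", sigmaA = 0, sigmaE = 1,
                      extra = stats::setNames(numeric(0), character(0)),
                      h2 = 0, logLik = 0, converged = TRUE,
                      boundary = TRUE, method = "eigen-profile")
  res <- snpScan(des, grm, vc0, g)
  ols <- stats::coef(stats::lm(y ~ ph$sex + M[, 5]))
  expect_equal(res$effect[5], unname(ols[3]), tolerance = 1e-10)

  # permuting all inputs identically changes nothing
  vc <- remlNull(des, grm)
  res1 <- snpScan(des, grm, vc, g)
  prm <- sample(n)
  ph2 <- ph[prm, ]
  g2 <- GenotypeData(M[prm, ])
  grm2 <- computeGrm(g2)
  des2 <- gwasDesign(ph2, "y", fixed = "sex")
  res2 <- snpScan(des2, grm2, remlNull(des2, grm2), g2)
  expect_equal(res2$effect, res1$effect, tolerance = 1e-8)
  expect_equal(res2$p, res1$p, tolerance = 1e-8)
})

test_that("markers collinear with the fixed effects get the NA sentinel", {
  set.seed(88)
  n <- 60
  M <- hwGenotypes(n, 10)
  grm <- computeGrm(GenotypeData(M))
  Mscan <- cbind(M, const = rep(1, n))
  gScan <- GenotypeData(Mscan)
  ph <- data.frame(animal = rownames(M), y = stats::rnorm(n))
  des <- gwasDesign(ph, "y")
  res <- snpScan(des, grm, remlNull(des, grm), gScan)
  expect_true(is.na(res$effect[res$marker == "const"]))
  expect_true(is.na(res$p[res$marker == "const"]))
  expect_false(anyNA(res$effect[res$marker != "const"]))
})

test_that("Bonferroni threshold and variance explained follow their formulas", {
  expect_equal(bonferroniThreshold(0.05, 44056), 5.9450, tolerance = 1e-4)
  expect_equal(floor(bonferroniThreshold(0.05, 44056) * 100) / 100, 5.94)
  expect_equal(bonferroniThreshold(0.05, 1), -log10(0.05))
  expect_equal(bonferroniThreshold(1, 1), 0)
  expect_error(bonferroniThreshold(0, 10), "alpha")

  expect_equal(varianceExplained(0.5, 1), 0.5)
  expect_equal(varianceExplained(0, 3), 0)
  expect_equal(varianceExplained(0.2, 2), 1.28)
  expect_equal(varianceExplained(0.2, 2, phenVar = 2), 0.64)
})

test_that("genomic inflation is calibrated and the QQ table uses k/(n+1)", {
  set.seed(99)
  z <- stats::rnorm(1e5)
  res <- data.frame(z = z, neglog10p = -log10(2 * stats::pnorm(-abs(z))))
  gi <- genomicInflation(res)
  expect_equal(gi$lambda, 1, tolerance = 0.02)
  # doubling every chi-square statistic doubles lambda
  res2 <- res; res2$z <- sqrt(2) * res$z
  expect_equal(genomicInflation(res2)$lambda, 2 * gi$lambda,
               tolerance = 1e-9)
  res3 <- data.frame(z = stats::rnorm(3),
                     neglog10p = c(0.5, 1.2, 0.1))
  expect_error(genomicInflation(res3), ">= 10")
  gi4 <- genomicInflation(res[1:200, ])
  expect_equal(gi4$qq$expected, -log10(seq_len(200) / 201))
  expect_equal(gi4$qq$observed, sort(res$neglog10p[1:200], decreasing = TRUE))
})
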