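test_that("founder assignment follows Hardy-Weinberg binomial sampling", {
  set.seed(9)
  big <- asPedigree(data.frame(id = sprintf("F%05d", 1:10000), sire = NA,
                               dam = NA, birth = 2000))
  d <- assignFounderGenotypes(big, maf = 0.5)
  tab <- tabulate(d + 1, 3) / 10000
  expect_equal(tab, c(0.25, 0.5, 0.25), tolerance = 0.03)
  # empirical frequency at maf 0.2 within 3 binomial SEs over 2N alleles
  d2 <- assignFounderGenotypes(big, maf = 0.2)
  se <- sqrt(0.2 * 0.8 / 20000)
  expect_lt(abs(mean(d2) / 2 - 0.2), 3 * se)
  expect_error(assignFounderGenotypes(big, maf = 0.7), "maf")
})

test_that("Mendelian transmission follows the Punnett expectations", {
  ped <- asPedigree(data.frame(id = c("S", "D", "K"), sire = c(NA, NA, "S"),
                               dam = c(NA, NA, "D"), birth = c(1, 1, 2)))
  # both parents dosage 2 -> offspring 2 with certainty
  for (r in 1:5)
    expect_equal(unname(dropLocus(ped, c(S = 2L, D = 2L), 0.1)["K"]), 2L)
  # het x het -> {0: .25, 1: .5, 2: .25}
  set.seed(4)
  kd <- replicate(4000, dropLocus(ped, c(S = 1L, D = 1L), 0.1)["K"])
  expect_equal(unname(tabulate(kd + 1, 3) / 4000), c(.25, .5, .25),
               tolerance = 0.05)
})

test_that("gene dropping is deterministic given the seed and the grid scales", {
  ped <- wfPedigree(20, 3, seed = 2)
  cfg <- geneDropConfig(list(A = cohortList(ped)), baselineYear = 2001,
                        mafGrid = c(0.1, 0.3), nRep = 25)
  t1 <- runGeneDropping(ped, cfg, seed = 33)
  t2 <- runGeneDropping(ped, cfg, seed = 33)
  expect_identical(t1@freq, t2@freq)
  expect_equal(length(t1@freq), 2)
  expect_equal(dim(t1@freq[[1]]), c(nrow(t1@cohorts), 25))
  t3 <- runGeneDropping(ped, cfg, seed = 34)
  expect_false(identical(t1@freq, t3@freq))
})

test_that("expected cohort frequency is constant across years (martingale)", {
  ped <- wfPedigree(60, 5, seed = 7)
  cfg <- geneDropConfig(list(A = cohortList(ped)), baselineYear = 2001,
                        mafGrid = 0.3, nRep = 1500)
  traj <- runGeneDropping(ped, cfg, seed = 21)
  Fm <- traj@freq[[1]]
  for (i in seq_len(nrow(Fm))) {
    se <- stats::sd(Fm[i, ]) / sqrt(ncol(Fm))
    expect_lt(abs(mean(Fm[i, ]) - 0.3), 3 * se + 1e-12)
  }
})

test_that("fixation absorbs along a single-ancestor chain", {
  n <- 8
  ped <- asPedigree(data.frame(
    id = sprintf("X%d", 1:n), sire = c(NA, sprintf("X%d", 1:(n - 1))),
    dam = c(NA, sprintf("X%d", 1:(n - 1))), birth = 1:n, genotyped = TRUE))
  cohorts <- lapply(as.character(1:n), function(y) sprintf("X%s", y))
  names(cohorts) <- 1:n
  cfg <- geneDropConfig(list(A = cohorts), baselineYear = 1,
                        mafGrid = 0.4, nRep = 400)
  traj <- runGeneDropping(ped, cfg, seed = 5)
  Fm <- traj@freq[[1]]
  for (r in seq_len(ncol(Fm))) {
    fixedAt <- which(Fm[, r] %in% c(0, 1))
    if (length(fixedAt)) {
      t0 <- min(fixedAt)
      expect_true(all(Fm[t0:nrow(Fm), r] == Fm[t0, r]))
    }
  }
})

test_that("drift envelope summarizes |dp| by realized baseline MAF", {
  ped <- wfPedigree(40, 4, seed = 3)
  cfg <- geneDropConfig(list(A = cohortList(ped)), baselineYear = 2001,
                        mafGrid = c(0.2, 0.4), nRep = 400)
  traj <- runGeneDropping(ped, cfg, seed = 8)
  env <- driftChangeDistribution(traj, 2001)
  tab <- env@table
  # identity horizon: |dp| exactly 0
  expect_true(all(tab$meanAbsDp[tab$year == 2001] == 0))
  expect_true(all(tab$maxAbsDp[tab$year == 2001] == 0))
  # quantiles non-decreasing in level, CI contains the mean, max dominates
  expect_true(all(tab$q99 >= tab$q95 - 1e-12))
  expect_true(all(tab$maxAbsDp >= tab$q99 - 1e-12))
  expect_true(all(tab$ciLow <= tab$meanAbsDp & tab$meanAbsDp <= tab$ciHigh))
  expect_true(all(tab$n >= 30))
})

test_that("injected Gaussian pseudo-trajectories give the folded-normal mean", {
  set.seed(6)
  nrep <- 40000; sigma <- 0.03; p0 <- 0.3
  Fm <- rbind(rep(p0, nrep), p0 + stats::rnorm(nrep, 0, sigma))
  traj <- methods::new("DriftTrajectories", maf = 0.3, freq = list(Fm),
                       cohorts = data.frame(line = "A", year = c(2015, 2016),
                                            n = 100),
                       nrep = as.integer(nrep), seed = 1L)
  env <- driftChangeDistribution(traj, 2015, binWidth = 0.5)
  m <- env@table$meanAbsDp[env@table$year == 2016]
  expect_equal(m, sigma * sqrt(2 / pi), tolerance = 0.02)
})

test_that("observed changes are placed correctly against the envelope", {
  ped <- wfPedigree(40, 3, seed = 13)
  cfg <- geneDropConfig(list(A = cohortList(ped)), baselineYear = 2001,
                        mafGrid = c(0.25, 0.45), nRep = 500)
  traj <- runGeneDropping(ped, cfg, seed = 2)
  env <- driftChangeDistribution(traj, 2001)
  obs <- data.frame(line = "A", marker = c("k1", "k2"), year = 2003,
                    absDp = c(0, 0.9), baselineMaf = c(0.25, 0.4))
  cmp <- compareToDrift(obs, env)
  expect_equal(cmp$perSnp$quantile[1], mean(
    env@samples[["A"]][[cmp$perSnp$bin[1]]][["2003"]] <= 0))
  expect_false(cmp$perSnp$exceedsMax[1])
  expect_true(cmp$perSnp$exceedsMax[2])
  expect_equal(cmp$summary$fracExceedsMax, 0.5)
})

test_that("the drift null is calibrated against drift-only observed data", {
  # same pedigree: observed marker changes are themselves pure drift, so
  # about 1% of SNP changes should fall beyond the 0.99 envelope quantile
  cfgS <- simConfig(nLines = 1, years = 2015:2018, nMarkers = 2000,
                    selection = "random")
  sim <- simulatePopulation(cfgS, seed = 17)
  ped <- sim$pedigree
  af <- alleleFreqByCohort(sim$genotypes, cohortList(ped, line = "A"),
                           line = "A")
  chg <- absChangeVsBaseline(af, 2015)
  chg <- chg[chg$year == 2018 & chg$baselineMaf > 0, ]
  cfg <- geneDropConfig(list(A = cohortList(ped)), baselineYear = 2015,
                        mafGrid = seq(0.05, 0.5, 0.05), nRep = 600)
  traj <- runGeneDropping(ped, cfg, seed = 18)
  env <- driftChangeDistribution(traj, 2015)
  cmp <- compareToDrift(chg, env)
  fracBeyond99 <- mean(cmp$perSnp$quantile > 0.99, na.rm = TRUE)
  expect_lt(fracBeyond99, 0.05)
  expect_lt(cmp$summary$fracExceedsMax, 0.02)
})
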