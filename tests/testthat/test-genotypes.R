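test_that("dosage TSV round-trips losslessly", {
  set.seed(2)
  M <- hwGenotypes(12, 8)
  M[sample(length(M), 5)] <- NA
  g <- GenotypeData(M)
  f <- withr::local_tempfile(fileext = ".tsv")
  fm <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypes(g, f, mapPath = fm)
  g2 <- readGenotypes(f, format = "tsv", mapPath = fm)
  expect_identical(dosages(g2), dosages(g))
  expect_equal(markerInfo(g2)[, c("marker", "chrom", "pos")],
               markerInfo(g)[, c("marker", "chrom", "pos")])
})

test_that("VCF genotypes are read as ALT-allele dosages", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tsnpA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tsnpB\tC\tT\t.\tPASS\t.\tGT\t./.\t0/1\t0/0",
    "2\t50\tsnpC\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0"), f)
  expect_warning(g <- readGenotypes(f, format = "vcf"), "multiallelic")
  M <- dosages(g)
  expect_equal(unname(M[, "snpA"]), c(0, 1, 2))
  expect_true(is.na(M["s1", "snpB"]))
  expect_equal(unname(M[c("s2", "s3"), "snpB"]), c(1, 0))
  expect_false("snpC" %in% colnames(M))
  expect_equal(markerInfo(g)$counted[markerInfo(g)$marker == "snpA"], "G")
})

test_that("QC missingness thresholds use strict inequality", {
  M10 <- matrix(rep(c(0, 1, 2), 10), 3, 10,
                dimnames = list(c("a", "b", "c"), sprintf("m%d", 1:10)))
  M10[1, 1] <- NA                     # 1/10 = 0.10 > 0.05 -> removed
  q <- qcGenotypes(GenotypeData(M10), markerMissMax = 1)
  expect_equal(q$report$animalsRemoved$id, "a")
  expect_equal(q$report$animalsRemoved$reason, "missingness")

  M20 <- matrix(rep(c(0, 2), 20), 2, 20, byrow = FALSE,
                dimnames = list(c("a", "b"), sprintf("m%d", 1:20)))
  M20[1, 1] <- NA                     # 1/20 = 0.05, strict ">" -> kept
  q2 <- qcGenotypes(GenotypeData(M20), markerMissMax = 1)
  expect_equal(nrow(q2$report$animalsRemoved), 0)
  expect_error(qcGenotypes(GenotypeData(M20), animalMissMax = 2),
               "is not TRUE")
})

test_that("exact duplicate genotypes keep the smallest id", {
  M <- rbind(b2 = c(0, 1, 2, NA), a1 = c(0, 1, 2, NA), c3 = c(2, 1, 0, 1))
  colnames(M) <- sprintf("m%d", 1:4)
  q <- qcGenotypes(GenotypeData(M), animalMissMax = 1, markerMissMax = 1)
  expect_equal(q$report$animalsRemoved$id, "b2")
  expect_true("a1" %in% rownames(dosages(q$genotypes)))
  # differing missing pattern is not a duplicate
  M2 <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, NA), c = c(2, 1, 0, 0))
  colnames(M2) <- sprintf("m%d", 1:4)
  q2 <- qcGenotypes(GenotypeData(M2), animalMissMax = 1, markerMissMax = 1)
  expect_equal(nrow(q2$report$animalsRemoved), 0)
})

test_that("opposing-homozygote rate removes pedigree-genotype conflicts", {
  ped <- asPedigree(data.frame(id = c("P", "K", "U"), sire = c(NA, "P", NA),
                               dam = NA, birth = c(1, 2, 1),
                               genotyped = TRUE))
  M <- rbind(P = rep(2, 10), K = c(rep(0, 3), rep(2, 7)),
             U = rep(1, 10))          # unrelated het keeps markers polymorphic
  M[1, 1] <- 1; M[2, 10] <- 1
  colnames(M) <- sprintf("m%d", 1:10)
  # K opposes P at markers 2,3 of 10 informative -> rate 0.2 > 0.1
  q <- qcGenotypes(GenotypeData(M), ped, mendelConflictMax = 0.1,
                   markerMissMax = 1)
  expect_equal(q$report$animalsRemoved$reason, "pedigree_conflict")
  expect_equal(q$report$animalsRemoved$id, "K")
  q2 <- qcGenotypes(GenotypeData(M), ped, mendelConflictMax = 0.5,
                    markerMissMax = 1)
  expect_equal(nrow(q2$report$animalsRemoved), 0)
})

test_that("monomorphic markers are removed and QC is idempotent", {
  set.seed(5)
  M <- hwGenotypes(30, 15)
  M[, 3] <- 2                         # monomorphic
  M[sample(length(M), 20)] <- NA
  g <- GenotypeData(M)
  q1 <- qcGenotypes(g)
  expect_true("s0003" %in% q1$report$markersRemoved$marker)
  q2 <- qcGenotypes(q1$genotypes)
  expect_identical(dosages(q2$genotypes), dosages(q1$genotypes))
  expect_equal(nrow(q2$report$animalsRemoved), 0)
  expect_equal(nrow(q2$report$markersRemoved), 0)
})

test_that("mean imputation fills missing cells and preserves marker means", {
  M <- rbind(a = c(0, 1), b = c(2, NA), c = c(NA, 1))
  colnames(M) <- c("m1", "m2")
  gi <- imputeMean(GenotypeData(M))
  D <- dosages(gi)
  expect_equal(D["c", "m1"], 1)       # mean of {0, 2}
  expect_equal(D["b", "m2"], 1)
  expect_equal(D["a", ], c(m1 = 0, m2 = 1))  # observed cells untouched
  expect_equal(colMeans(D), colMeans(M, na.rm = TRUE))
  # complete matrix is returned unchanged
  Mc <- rbind(a = c(0, 1), b = c(2, 1)); colnames(Mc) <- c("m1", "m2")
  expect_identical(dosages(imputeMean(GenotypeData(Mc))), Mc)
  Mall <- rbind(a = c(NA, 1), b = c(NA, 0)); colnames(Mall) <- c("m1", "m2")
  expect_error(imputeMean(GenotypeData(Mall)), "all-missing")
})

test_that("cohort allele frequencies use non-missing calls only", {
  M <- rbind(a = c(1, 2), b = c(2, NA), c = c(0, 0))
  colnames(M) <- c("m1", "m2")
  g <- GenotypeData(M)
  af <- alleleFreqByCohort(g, list(`2015` = c("a", "b"), `2016` = "c"),
                           line = "A")
  expect_equal(af$p[af$year == 2015 & af$marker == "m1"], 0.75)
  expect_equal(af$p[af$year == 2015 & af$marker == "m2"], 1.0)  # {2, NA}
  expect_equal(af$n[af$year == 2015 & af$marker == "m2"], 1L)
  expect_equal(af$p[af$year == 2016 & af$marker == "m1"], 0)
  expect_warning(alleleFreqByCohort(g, list(`2015` = "a", `2017` = "zz")),
                 "empty cohort")

  # allele-label flip equivariance: p -> 1 - p
  gFlip <- GenotypeData(2 - M)
  afF <- alleleFreqByCohort(gFlip, list(`2015` = c("a", "b")), line = "A")
  af1 <- alleleFreqByCohort(g, list(`2015` = c("a", "b")), line = "A")
  expect_equal(afF$p, 1 - af1$p)
})
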