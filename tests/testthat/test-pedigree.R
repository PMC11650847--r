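test_that("readPedigree parses, orders and augments a minimal file", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,birth_date,sex,line,genotyped",
               "C,F,M,2002,male,A,1",
               "F,0,0,2000,male,A,0",
               "M,,NA,2000-06-15,female,A,0"), f)
  ped <- readPedigree(f)
  rec <- pedRecords(ped)
  expect_equal(nrow(rec), 3)
  expect_true(which(rec$id == "C") > max(which(rec$id %in% c("F", "M"))))
  expect_setequal(founders(ped), c("F", "M"))
  doy <- as.integer(format(as.Date("2000-06-15"), "%j"))
  expect_equal(rec$birth[rec$id == "M"], 2000 + (doy - 1) / 365.25,
               tolerance = 1e-9)

  # parents absent from the id column become founder records
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,birth_date",
               "K1,S9,D8,2001", "K2,S9,D7,2001"), f2)
  ped2 <- readPedigree(f2)
  expect_setequal(ped2@autoAdded,
                  setdiff(c("S9", "D8", "D7"), c("K1", "K2")))
  expect_equal(length(ped2@autoAdded), 3)
})

test_that("pedigree validation rejects duplicates, cycles and date conflicts", {
  expect_error(asPedigree(data.frame(id = c("A", "A"), sire = NA, dam = NA)),
               "duplicate")
  expect_error(asPedigree(data.frame(id = "C", sire = "C", dam = NA)),
               "cycle")
  expect_error(asPedigree(data.frame(id = c("A", "B"), sire = c("B", "A"),
                                     dam = NA)), "cycle")
  df <- data.frame(id = c("P", "K"), sire = c(NA, "P"), dam = NA,
                   birth = c(2005, 2003))
  expect_error(asPedigree(df), "born at/after")
  expect_warning(asPedigree(df, allowDateConflicts = TRUE), "born at/after")
})

test_that("additive relationships match textbook values", {
  ped <- asPedigree(data.frame(id = c("F", "M"), sire = NA, dam = NA,
                               birth = 1))
  A <- additiveRelationship(ped)
  expect_equal(unname(A), diag(2))

  sib <- asPedigree(data.frame(id = c("S", "D", "A1", "A2"),
                               sire = c(NA, NA, "S", "S"),
                               dam = c(NA, NA, "D", "D"), birth = c(1, 1, 2, 2)))
  expect_equal(additiveRelationship(sib, c("A1", "A2"))["A1", "A2"], 0.5)

  # offspring of a full-sib mating: F = 0.25
  fsm <- asPedigree(data.frame(id = c("S", "D", "A1", "A2", "X"),
                               sire = c(NA, NA, "S", "S", "A1"),
                               dam = c(NA, NA, "D", "D", "A2"),
                               birth = c(1, 1, 2, 2, 3)))
  expect_equal(unname(diag(additiveRelationship(fsm, "X"))), 1.25)
  expect_equal(unname(inbreedingCoef(fsm, "X")), 0.25)
  expect_error(additiveRelationship(fsm, "nope"), "not in pedigree")
})

test_that("subset A equals the full-pedigree oracle on random pedigrees", {
  set.seed(11)
  for (rep in 1:4) {
    ped <- randomPedigree(sample(50:200, 1))
    rec <- pedRecords(ped)
    Afull <- tabularOracle(rec)
    ids <- sample(rec$id, 20)
    expect_equal(additiveRelationship(ped, ids), Afull[ids, ids],
                 tolerance = 1e-12)
  }
})

test_that("mean kinship by cohort handles the hand-computed cases", {
  df <- data.frame(id = c("S", "D", "A1", "A2", "U"),
                   sire = c(NA, NA, "S", "S", NA),
                   dam = c(NA, NA, "D", "D", NA),
                   birth = c(1, 1, 2, 2, 2), genotyped = TRUE)
  ped <- asPedigree(df)
  k <- meanKinshipByYear(ped, years = 2)
  # pairs {A1,A2}=0.5, {A1,U}=0, {A2,U}=0 -> f = 0.5 * (0.5/3)
  expect_equal(k$f, 0.5 * (0.5 / 3))
  expect_equal(k$nPairs, 3)

  twoSibs <- meanKinshipByYear(asPedigree(df[1:4, ]), years = 2)
  expect_equal(twoSibs$f, 0.25)
  unrel <- meanKinshipByYear(asPedigree(
    data.frame(id = c("X", "Y"), sire = NA, dam = NA, birth = 5,
               genotyped = TRUE)))
  expect_equal(unrel$f, 0)

  # invariant to permutation of record order
  perm <- asPedigree(df[c(2, 1, 5, 4, 3), ])
  expect_equal(meanKinshipByYear(perm, years = 2)$f, k$f)

  # undersized cohorts are dropped with a warning
  expect_warning(res <- meanKinshipByYear(ped, years = c(0, 2)),
                 "dropping")
  expect_equal(res$year, 2)
})

test_that("generation interval averages parent-offspring birth gaps", {
  ped <- asPedigree(data.frame(id = c("S", "D", "K"),
                               sire = c(NA, NA, "S"), dam = c(NA, NA, "D"),
                               birth = c(2000, 2000, 2002), genotyped = TRUE))
  expect_equal(as.numeric(generationInterval(ped, "K")), 2)
  mix <- asPedigree(data.frame(id = c("S", "D", "K"),
                               sire = c(NA, NA, "S"), dam = c(NA, NA, "D"),
                               birth = c(2003, 2002, 2004)))
  expect_equal(as.numeric(generationInterval(mix, "K")), 1.5)
  noLink <- asPedigree(data.frame(id = "F", sire = NA, dam = NA, birth = 1))
  expect_error(generationInterval(noLink, "F"), "no usable")
})

test_that("Ne estimation follows the inbreeding-rate identities", {
  # noiseless geometric series recovers dF exactly
  ser <- data.frame(year = 2000:2009, f = 1 - (1 - 0.005)^(0:9))
  est <- estimateNe(ser, L = 1)
  expect_equal(est@deltaFYear, 0.005, tolerance = 1e-12)
  expect_equal(est@ne, 100, tolerance = 1e-9)
  expect_equal(est@deltaFGen, est@generationInterval * est@deltaFYear)
  expect_equal(est@ne, 1 / (2 * est@deltaFGen))

  # constant kinship: Ne undefined with a flag, not an error
  flat <- estimateNe(data.frame(year = 1:4, f = 0.02), L = 1.4)
  expect_false(flat@defined)
  expect_true(is.na(flat@ne))

  expect_error(estimateNe(ser[1:2, ], 1), "at least 3")
  expect_error(estimateNe(data.frame(year = 1:3, f = c(0.1, 0.5, 1)), 1),
               "< 1")

  # report round-trips through JSON
  f <- withr::local_tempfile(fileext = ".json")
  writeNeReport(est, f)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$ne, 100, tolerance = 1e-9)
})
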