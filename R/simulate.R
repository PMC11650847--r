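#' Breeding-population simulation configuration
#'
#' Defaults emulate a closed maternal pig line under index truncation
#' selection: seven genotyped birth-year cohorts (2015-2021) with
#' overlapping generations (parent ages 1 or 2 years, mean 1.4), two lines
#' with a shared marker map and counted alleles, pleiotropic QTL behind a
#' linear selection index, and a per-year genotyped fraction. Markers are
#' unlinked; founder frequencies are uniform on `founderMafRange`.
#'
#' @param nLines number of independent lines (shared marker map).
#' @param years genotyped birth-year cohorts.
#' @param preYears founder cohorts created before `years[1]`.
#' @param nSiresPerYear,nDamsPerYear parents selected each year.
#' @param litterSize offspring per dam per year.
#' @param parentAgeProbs named numeric: probability mass over parent age
#'   classes in years (default `c("1" = 0.6, "2" = 0.4)`, mean 1.4); the
#'   parent team is split across age classes in these proportions.
#' @param nMarkers biallelic SNPs (unlinked, spread over 18 chromosomes).
#' @param nQtl markers that are causal (shared set across traits).
#' @param founderMafRange uniform range of founder counted-allele
#'   frequencies.
#' @param h2 per-trait heritabilities.
#' @param phenVar per-trait phenotypic variances.
#' @param geneticCorr genetic correlation matrix across traits.
#' @param indexWeights selection-index weights over traits.
#' @param selection `"index_truncation"` (truncation on the true index) or
#'   `"random"` (pure drift).
#' @param matingDesign `"litters"` (each team dam produces one litter of
#'   `litterSize`; the default, matching a pig breeding scheme) or
#'   `"random_pairs"` (every offspring draws an independent sire and dam
#'   from the teams -- multinomial offspring counts, the idealized
#'   random-mating population used to validate drift expectations).
#' @param genotypedFraction fraction of each study cohort genotyped.
#' @param batchVarFrac,litterVarFrac fractions of phenotypic variance
#'   given to the year-batch and litter random effects.
#' @param qtlOverrides optional list of `list(marker =, effects =)` to
#'   plant specific (e.g. antagonistic) QTL after scaling.
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(nLines = 2, years = 2015:2021, preYears = 2,
                      nSiresPerYear = 20, nDamsPerYear = 100,
                      litterSize = 6,
                      parentAgeProbs = c("1" = 0.6, "2" = 0.4),
                      nMarkers = 3000, nQtl = 100,
                      founderMafRange = c(0.01, 0.5),
                      h2 = c(0.3, 0.3), phenVar = c(1, 1),
                      geneticCorr = diag(length(h2)),
                      indexWeights = rep(1, length(h2)),
                      selection = c("index_truncation", "random"),
                      matingDesign = c("litters", "random_pairs"),
                      genotypedFraction = 0.67,
                      batchVarFrac = 0.05, litterVarFrac = 0.05,
                      qtlOverrides = NULL) {
  selection <- match.arg(selection)
  matingDesign <- match.arg(matingDesign)
  nt <- length(h2)
  stopifnot(all(h2 >= 0), all(h2 <= 1), length(phenVar) == nt,
            nrow(geneticCorr) == nt, length(indexWeights) == nt,
            genotypedFraction > 0, genotypedFraction <= 1,
            preYears >= max(as.integer(names(parentAgeProbs))),
            abs(sum(parentAgeProbs) - 1) < 1e-8,
            nQtl <= nMarkers,
            all(h2 + batchVarFrac + litterVarFrac <= 1))
  ev <- eigen(geneticCorr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("geneticCorr not positive semi-definite")
  structure(as.list(environment()), class = "SimConfig")
}

# gamete dosage contribution from parent dosage rows (unlinked loci)
.gamete <- function(P) {
  (P == 2) + (P == 1) * (matrix(stats::runif(length(P)), nrow(P)) < 0.5)
}

#' Simulate a pedigreed breeding population
#'
#' Founder cohorts are drawn in Hardy-Weinberg proportions at the shared
#' founder frequencies; each subsequent year a parent team (split over age
#' classes per `parentAgeProbs`) is chosen from the age-eligible
#' candidates -- by truncation on the true selection index or at random --
#' and litters are produced by per-marker Mendelian sampling. Phenotypes
#' are mean + sex + year-batch + litter + true breeding value + residual,
#' at the configured heritabilities. Deterministic given `seed`.
#'
#' @param cfg a [simConfig()].
#' @param seed integer seed.
#' @return list with elements `pedigree` ([Pedigree-class], all lines
#'   combined), `genotypes` ([GenotypeData-class], genotyped animals
#'   only), `phenotypes` (data.frame: animal, line, year, sex, batch,
#'   litter, one column per trait, `index`), and `truth` (list: `qtl`
#'   effects table, `tbv` per animal, `founderFreqs`, `indexWeights`,
#'   `seed`).
#' @export
simulatePopulation <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(seed)
  nm <- cfg$nMarkers; nt <- length(cfg$h2)
  markers <- sprintf("M%05d", seq_len(nm))
  # 18 contiguous chromosome blocks, unlinked loci 1 kb apart
  block <- if (nm >= 18) cut(seq_len(nm), 18, labels = FALSE) else rep(1L, nm)
  map <- data.frame(marker = markers, chrom = sprintf("%02d", block),
                    pos = stats::ave(seq_len(nm), block, FUN = seq_along) * 1000L,
                    stringsAsFactors = FALSE)
  pFound <- stats::runif(nm, cfg$founderMafRange[1], cfg$founderMafRange[2])

  # shared trait architecture: one QTL set, correlated effects
  qtlIdx <- sort(sample.int(nm, cfg$nQtl))
  raw <- matrix(stats::rnorm(cfg$nQtl * nt), cfg$nQtl, nt)
  L <- chol(cfg$geneticCorr + diag(1e-10, nt))
  E <- raw %*% L
  for (tr in seq_len(nt)) {
    tgt <- cfg$h2[tr] * cfg$phenVar[tr]
    cur <- sum(2 * pFound[qtlIdx] * (1 - pFound[qtlIdx]) * E[, tr]^2)
    E[, tr] <- E[, tr] * sqrt(tgt / cur)
  }
  qtl <- data.frame(marker = markers[qtlIdx],
                    matrix(E, ncol = nt,
                           dimnames = list(NULL, paste0("trait", seq_len(nt)))),
                    stringsAsFactors = FALSE)
  if (!is.null(cfg$qtlOverrides)) {
    for (ov in cfg$qtlOverrides) {
      j <- match(ov$marker, qtl$marker)
      if (is.na(j)) {
        qtl <- rbind(qtl, data.frame(marker = ov$marker,
                                     matrix(ov$effects, ncol = nt,
                                            dimnames = list(NULL, paste0("trait", seq_len(nt))))))
      } else qtl[j, -1] <- as.list(ov$effects)
    }
    qtl <- qtl[order(match(qtl$marker, markers)), ]
  }
  qtl$indexEffect <- as.numeric(as.matrix(qtl[, paste0("trait", seq_len(nt))])
                                %*% cfg$indexWeights)
  qtlPos <- match(qtl$marker, markers)
  Emat <- as.matrix(qtl[, paste0("trait", seq_len(nt)), drop = FALSE])

  ageClasses <- as.integer(names(cfg$parentAgeProbs))
  nOff <- cfg$nDamsPerYear * cfg$litterSize
  teamSplit <- function(total) {
    k <- floor(total * cfg$parentAgeProbs)
    rem <- total - sum(k)
    if (rem > 0) k[seq_len(rem)] <- k[seq_len(rem)] + 1
    k
  }
  lineLabels <- LETTERS[seq_len(cfg$nLines)]
  allRec <- list(); allGeno <- list(); allTbv <- list(); allPhe <- list()
  for (li in seq_len(cfg$nLines)) {
    ln <- lineLabels[li]
    yearsAll <- c(cfg$years[1] - rev(seq_len(cfg$preYears)), cfg$years)
    nTot <- nOff * length(yearsAll)
    Gm <- matrix(0L, nTot, nm)
    rec <- data.frame(id = character(nTot), sire = NA_character_,
                      dam = NA_character_, birth = NA_real_,
                      sex = NA_character_, line = ln, genotyped = FALSE,
                      stringsAsFactors = FALSE)
    tbv <- matrix(0, nTot, nt)
    idx <- stats::setNames(numeric(0), character(0)) # id -> row
    cnt <- 0L
    litterId <- character(nTot)
    for (y in yearsAll) {
      isFounderYear <- y < cfg$years[1]
      rows <- cnt + seq_len(nOff)
      ids <- sprintf("%s%06d", ln, rows)
      if (isFounderYear) {
        Gm[rows, ] <- matrix(stats::rbinom(nOff * nm, 2, rep(pFound, each = nOff)),
                             nOff, nm)
        rec$sire[rows] <- NA; rec$dam[rows] <- NA
        litterId[rows] <- NA_character_
      } else {
        pickTeam <- function(sex, total) {
          need <- teamSplit(total)
          team <- character(0)
          for (k in seq_along(ageClasses)) {
            if (need[k] == 0) next
            cand <- rec$id[!is.na(rec$birth) & rec$birth == y - ageClasses[k] &
                             rec$sex == sex]
            if (length(cand) < need[k])
              stop("infeasible selection: ", need[k], " ", sex,
                   "(s) of age ", ageClasses[k], " needed in year ", y,
                   ", only ", length(cand), " candidates")
            if (cfg$selection == "index_truncation") {
              sc <- as.numeric(tbv[idx[cand], , drop = FALSE] %*% cfg$indexWeights)
              team <- c(team, cand[order(-sc)[seq_len(need[k])]])
            } else {
              team <- c(team, sample(cand, need[k]))
            }
          }
          team
        }
        sires <- pickTeam("male", cfg$nSiresPerYear)
        dams <- pickTeam("female", cfg$nDamsPerYear)
        if (cfg$matingDesign == "random_pairs") {
          damOf <- sample(dams, nOff, replace = TRUE)
          sireOf <- sample(sires, nOff, replace = TRUE)
        } else {
          damOf <- rep(dams, each = cfg$litterSize)
          sireOfDam <- sample(sires, length(dams), replace = TRUE)
          sireOf <- rep(sireOfDam, each = cfg$litterSize)
        }
        Gs <- Gm[idx[sireOf], , drop = FALSE]
        Gd <- Gm[idx[damOf], , drop = FALSE]
        Gm[rows, ] <- .gamete(Gs) + .gamete(Gd)
        rec$sire[rows] <- sireOf
        rec$dam[rows] <- damOf
        litterId[rows] <- paste0(damOf, "_", y)
      }
      rec$id[rows] <- ids
      rec$birth[rows] <- y
      rec$sex[rows] <- rep_len(c("male", "female"), nOff)
      if (!isFounderYear)
        rec$genotyped[rows] <- seq_len(nOff) %in%
          sample.int(nOff, round(cfg$genotypedFraction * nOff))
      tbv[rows, ] <- Gm[rows, qtlPos, drop = FALSE] %*% Emat
      idx[ids] <- rows
      cnt <- cnt + nOff
    }
    rownames(Gm) <- rec$id
    # phenotypes for genotyped study-cohort animals
    sel <- rec$genotyped
    batch <- paste0(ln, "_", rec$birth[sel])
    litter <- litterId[sel]
    phe <- data.frame(animal = rec$id[sel], line = ln,
                      year = rec$birth[sel], sex = rec$sex[sel],
                      batch = batch, litter = litter,
                      stringsAsFactors = FALSE)
    bLev <- unique(batch); lLev <- unique(litter)
    for (tr in seq_len(nt)) {
      vB <- cfg$batchVarFrac * cfg$phenVar[tr]
      vL <- cfg$litterVarFrac * cfg$phenVar[tr]
      vE <- cfg$phenVar[tr] * (1 - cfg$h2[tr] - cfg$batchVarFrac -
                                 cfg$litterVarFrac)
      bEff <- stats::setNames(stats::rnorm(length(bLev), 0, sqrt(vB)), bLev)
      lEff <- stats::setNames(stats::rnorm(length(lLev), 0, sqrt(vL)), lLev)
      sexEff <- ifelse(phe$sex == "male", 0.1 * sqrt(cfg$phenVar[tr]),
                       -0.1 * sqrt(cfg$phenVar[tr]))
      phe[[paste0("trait", tr)]] <- tbv[idx[phe$animal], tr] +
        bEff[batch] + lEff[litter] + sexEff +
        stats::rnorm(nrow(phe), 0, sqrt(vE))
    }
    phe$index <- as.numeric(tbv[idx[phe$animal], , drop = FALSE] %*%
                              cfg$indexWeights)
    allRec[[li]] <- rec
    allGeno[[li]] <- Gm[sel, , drop = FALSE]
    allTbv[[li]] <- data.frame(animal = rec$id, line = ln,
                               tbv, index = as.numeric(tbv %*% cfg$indexWeights),
                               stringsAsFactors = FALSE)
    names(allTbv[[li]])[3:(2 + nt)] <- paste0("trait", seq_len(nt))
    allPhe[[li]] <- phe
  }
  recAll <- do.call(rbind, allRec)
  ped <- asPedigree(recAll)
  Gall <- do.call(rbind, allGeno)
  colnames(Gall) <- markers
  storage.mode(Gall) <- "double"
  geno <- GenotypeData(Gall, map = map, counted = "A1")
  truth <- list(qtl = qtl, tbv = do.call(rbind, allTbv),
                founderFreqs = stats::setNames(pFound, markers),
                indexWeights = cfg$indexWeights, seed = seed)
  list(pedigree = ped, genotypes = geno,
       phenotypes = do.call(rbind, allPhe), truth = truth)
}

#' Plant a pleiotropic (possibly antagonistic) QTL in a truth architecture
#'
#' Sets the per-trait effects of one marker and recomputes its index
#' effect as the weighted sum; with opposite-sign effects and matching
#' weights the index effect cancels (the dilution scenario).
#'
#' @param truth the `truth` element of [simulatePopulation()] output.
#' @param marker marker id.
#' @param effects numeric vector of per-trait additive effects.
#' @return updated truth list.
#' @export
plantAntagonisticQtl <- function(truth, marker, effects) {
  nt <- length(truth$indexWeights)
  stopifnot(length(effects) == nt)
  j <- match(marker, truth$qtl$marker)
  row <- data.frame(marker = marker,
                    matrix(effects, ncol = nt,
                           dimnames = list(NULL, paste0("trait", seq_len(nt)))),
                    indexEffect = sum(effects * truth$indexWeights),
                    stringsAsFactors = FALSE)
  if (is.na(j)) truth$qtl <- rbind(truth$qtl, row) else truth$qtl[j, ] <- row
  truth
}

#' True breeding values implied by genotypes and a truth architecture
#'
#' @param geno a [GenotypeData-class].
#' @param truth truth list with a `qtl` effects table.
#' @return data.frame: animal, one column per trait, `index`.
#' @export
breedingValues <- function(geno, truth) {
  M <- dosages(geno)
  q <- truth$qtl[truth$qtl$marker %in% colnames(M), ]
  tcols <- grep("^trait", names(q), value = TRUE)
  B <- M[, q$marker, drop = FALSE] %*% as.matrix(q[, tcols, drop = FALSE])
  data.frame(animal = rownames(M), B,
             index = as.numeric(B %*% truth$indexWeights),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a simulated dataset to plain-text files
#'
#' Pedigree CSV, dosage TSV plus marker-map TSV, phenotype TSV and truth
#' JSON; round-trips through [readPedigree()] / [readGenotypes()].
#'
#' @param sim output of [simulatePopulation()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
writeDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pedigree = file.path(dir, "pedigree.csv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             map = file.path(dir, "markers.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.json"))
  rec <- pedRecords(sim$pedigree)
  out <- data.frame(id = rec$id, sire = ifelse(is.na(rec$sire), "0", rec$sire),
                    dam = ifelse(is.na(rec$dam), "0", rec$dam),
                    birth_date = rec$birth, sex = rec$sex, line = rec$line,
                    genotyped = as.integer(rec$genotyped))
  utils::write.table(out, paths["pedigree"], sep = ",", quote = FALSE,
                     row.names = FALSE)
  writeGenotypes(sim$genotypes, paths["genotypes"], mapPath = paths["map"])
  utils::write.table(sim$phenotypes, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(qtl = sim$truth$qtl,
         indexWeights = sim$truth$indexWeights,
         founderFreqs = as.list(sim$truth$founderFreqs),
         seed = sim$truth$seed),
    paths["truth"], auto_unbox = TRUE, digits = NA, dataframe = "rows")
  paths
}
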