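#' Gene-dropping configuration
#'
#' @param cohorts nested named list: line label -> calendar year (as name)
#'   -> genotyped animal ids, e.g. from [cohortList()] per line.
#' @param baselineYear calendar year the drift changes are measured from.
#' @param mafGrid founder minor-allele-frequency grid (default 0.01 to 0.50
#'   in steps of 0.01).
#' @param nRep replicates per grid value (default 1000).
#' @return list of class `GeneDropConfig`.
#' @export
geneDropConfig <- function(cohorts, baselineYear,
                           mafGrid = seq(0.01, 0.50, by = 0.01),
                           nRep = 1000) {
  stopifnot(all(mafGrid > 0), all(mafGrid <= 0.5), nRep >= 1,
            is.list(cohorts), length(cohorts) >= 1)
  if (is.null(names(cohorts))) stop("cohorts must be named by line")
  structure(list(cohorts = cohorts, baselineYear = baselineYear,
                 mafGrid = mafGrid, nRep = as.integer(nRep)),
            class = "GeneDropConfig")
}

# deterministic 31-bit stream seed per grid index
derivedSeed <- function(root, k) {
  as.integer((as.numeric(root) * 65537 + k * 262143) %% 2147483629 + 1)
}

#' Assign founder genotypes for one gene-drop replicate
#'
#' Each founder (both parents unknown) receives two alleles drawn
#' independently, carrier with probability `maf` (Hardy-Weinberg sampling);
#' the dosage is the carrier-allele count.
#'
#' @param ped a [Pedigree-class].
#' @param maf founder carrier-allele frequency, in (0, 0.5].
#' @return named integer vector of founder dosages.
#' @export
assignFounderGenotypes <- function(ped, maf) {
  stopifnot(maf > 0, maf <= 0.5)
  f <- founders(ped)
  stats::setNames(stats::rbinom(length(f), 2, maf), f)
}

#' Drop one biallelic locus through the pedigree
#'
#' Reference (pure-R) Mendelian transmission for a single replicate: each
#' non-founder receives one uniformly chosen allele from each parent; an
#' unknown parent side draws a fresh founder allele (carrier with
#' probability `maf`), i.e. a unique phantom founder. For unlinked single
#' loci, transmission depends on the parent only through its dosage.
#'
#' @param ped a [Pedigree-class].
#' @param founderGenotypes named dosages for all founders, e.g. from
#'   [assignFounderGenotypes()].
#' @param maf carrier frequency used for phantom (unknown-side) alleles.
#' @return named integer dosage vector over all animals.
#' @export
dropLocus <- function(ped, founderGenotypes, maf) {
  rec <- ped@records
  pos <- stats::setNames(seq_len(nrow(rec)), rec$id)
  d <- integer(nrow(rec))
  gamete <- function(pd) {
    if (pd == 2L) 1L else if (pd == 0L) 0L else stats::rbinom(1, 1, 0.5)
  }
  for (i in seq_len(nrow(rec))) {
    s <- rec$sire[i]; m <- rec$dam[i]
    if (is.na(s) && is.na(m)) {
      d[i] <- founderGenotypes[[rec$id[i]]]
    } else {
      a1 <- if (is.na(s)) stats::rbinom(1, 1, maf) else gamete(d[pos[s]])
      a2 <- if (is.na(m)) stats::rbinom(1, 1, maf) else gamete(d[pos[m]])
      d[i] <- a1 + a2
    }
  }
  stats::setNames(d, rec$id)
}

#' Run gene dropping over a MAF grid
#'
#' For every grid value, `nRep` independent single-locus drops through the
#' pedigree (compiled kernel), with cohort allele frequencies computed over
#' the configured genotyped cohorts exactly as [alleleFreqByCohort()] does
#' on real data. Deterministic given `seed`: each grid value uses its own
#' derived stream, so grid batches are order-independent.
#'
#' @param ped a [Pedigree-class].
#' @param cfg a [geneDropConfig()].
#' @param seed integer root seed.
#' @return a [DriftTrajectories-class].
#' @export
runGeneDropping <- function(ped, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "GeneDropConfig"))
  rec <- ped@records
  pos <- stats::setNames(seq_len(nrow(rec)), rec$id)
  si <- ifelse(is.na(rec$sire), 0L, pos[rec$sire]) - 1L
  di <- ifelse(is.na(rec$dam), 0L, pos[rec$dam]) - 1L
  cohTab <- do.call(rbind, lapply(names(cfg$cohorts), function(ln) {
    yrs <- names(cfg$cohorts[[ln]])
    data.frame(line = ln, year = as.numeric(yrs),
               n = lengths(cfg$cohorts[[ln]]), stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  if (any(cohTab$n == 0)) stop("empty cohort in gene-drop config")
  idx <- unlist(lapply(names(cfg$cohorts), function(ln)
    lapply(cfg$cohorts[[ln]], function(ids) {
      j <- pos[ids]
      if (anyNA(j)) stop("cohort id not in pedigree")
      unname(j)
    })), recursive = FALSE)
  freq <- vector("list", length(cfg$mafGrid))
  for (k in seq_along(cfg$mafGrid)) {
    set.seed(derivedSeed(seed, k))
    D <- cpp_gene_drop(as.integer(si), as.integer(di), cfg$mafGrid[k],
                       cfg$nRep)
    Fm <- matrix(0, nrow(cohTab), cfg$nRep)
    for (c in seq_along(idx))
      Fm[c, ] <- colSums(D[idx[[c]], , drop = FALSE]) / (2 * length(idx[[c]]))
    freq[[k]] <- Fm
  }
  methods::new("DriftTrajectories", maf = cfg$mafGrid, freq = freq,
               cohorts = cohTab, nrep = as.integer(cfg$nRep),
               seed = as.integer(seed))
}

#' Distribution of allele-frequency change under pure drift
#'
#' Bins replicates by their REALIZED baseline-cohort MAF (folded to <= 0.5;
#' right-closed bins of width `binWidth`) -- the observed SNPs are
#' conditioned on their baseline MAF, so the null is conditioned the same
#' way. Replicates fixed in the baseline cohort are excluded and counted.
#' Per (line, bin, horizon year) the |dp| summaries are the mean, a
#' normal-approximation 95% CI of the mean, upper quantiles and the max.
#' Bins with fewer than `minBin` replicates are merged with a neighbor and
#' flagged.
#'
#' @param traj a [DriftTrajectories-class].
#' @param baselineYear baseline calendar year (must be a cohort year).
#' @param binWidth MAF bin width (default 0.01).
#' @param quantiles upper quantile levels to report (default 0.95, 0.99).
#' @param minBin minimum replicates per bin before merging (default 30).
#' @return a [DriftEnvelope-class].
#' @export
driftChangeDistribution <- function(traj, baselineYear, binWidth = 0.01,
                                    quantiles = c(0.95, 0.99), minBin = 30) {
  coh <- traj@cohorts
  lines <- unique(coh$line)
  tabs <- list(); samples <- list(); nFixed <- stats::setNames(
    numeric(length(lines)), lines)
  for (ln in lines) {
    rows <- which(coh$line == ln)
    yrs <- coh$year[rows]
    b <- rows[match(baselineYear, yrs)]
    if (is.na(b)) stop("baseline year absent for line ", ln)
    p0 <- unlist(lapply(traj@freq, function(Fm) Fm[b, ]))
    keep <- p0 > 0 & p0 < 1
    nFixed[ln] <- sum(!keep)
    maf0 <- pmin(p0[keep], 1 - p0[keep])
    bin <- ceiling(maf0 / binWidth - 1e-12)
    # merge small bins left-to-right into groups of >= minBin
    ub <- sort(unique(bin))
    cnt <- table(factor(bin, levels = ub))
    grp <- integer(length(ub)); gi <- 1L; acc <- 0
    for (j in seq_along(ub)) {
      grp[j] <- gi; acc <- acc + cnt[j]
      if (acc >= minBin && j < length(ub)) { gi <- gi + 1L; acc <- 0 }
    }
    if (acc < minBin && acc > 0 && gi > 1L) grp[grp == gi] <- gi - 1L
    gmap <- stats::setNames(grp, ub)
    g <- gmap[as.character(bin)]
    merged <- as.integer(names(which(table(grp) > 1)))
    glo <- tapply((ub - 1) * binWidth, grp, min)
    ghi <- tapply(ub * binWidth, grp, max)
    samples[[ln]] <- list()
    for (gg in sort(unique(grp))) {
      lab <- sprintf("(%.2f,%.2f]", glo[as.character(gg)],
                     ghi[as.character(gg)])
      samples[[ln]][[lab]] <- list()
    }
    for (yi in seq_along(rows)) {
      py <- unlist(lapply(traj@freq, function(Fm) Fm[rows[yi], ]))
      adp <- abs(py[keep] - p0[keep])
      for (gg in sort(unique(grp))) {
        sel <- g == gg
        x <- adp[sel]
        nG <- length(x)
        m <- mean(x); s <- stats::sd(x)
        qs <- stats::quantile(x, quantiles, names = FALSE)
        lab <- sprintf("(%.2f,%.2f]", glo[as.character(gg)],
                       ghi[as.character(gg)])
        tabs[[length(tabs) + 1]] <- data.frame(
          line = ln, bin = lab,
          binLow = as.numeric(glo[as.character(gg)]),
          binHigh = as.numeric(ghi[as.character(gg)]),
          year = yrs[yi], n = nG, meanAbsDp = m,
          ciLow = m - 1.96 * s / sqrt(nG), ciHigh = m + 1.96 * s / sqrt(nG),
          q95 = qs[match(0.95, quantiles)], q99 = qs[match(0.99, quantiles)],
          maxAbsDp = max(x), merged = gg %in% merged,
          stringsAsFactors = FALSE)
        samples[[ln]][[lab]][[as.character(yrs[yi])]] <- x
      }
    }
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  methods::new("DriftEnvelope", table = tab, samples = samples,
               baselineYear = as.numeric(baselineYear),
               binWidth = binWidth, nFixed = nFixed)
}

#' Compare observed allele-frequency changes with the drift envelope
#'
#' Places every observed SNP change in its baseline-MAF bin of the drift
#' envelope: the quantile of the replicate |dp| distribution it falls at,
#' and whether it exceeds the replicate maximum. Per (bin, horizon year)
#' the observed mean |dp| is tested against the drift mean with a
#' two-sided two-sample z test.
#'
#' @param observed AfChangeTable from [absChangeVsBaseline()] (columns
#'   `line`, `marker`, `year`, `absDp`, `baselineMaf`).
#' @param env a [DriftEnvelope-class] built with the same baseline year.
#' @return list: `perSnp` (data.frame with bin, quantile, exceedsMax,
#'   nearestBin flag), `perBin` (observed vs drift means with z and p),
#'   `summary` (fraction of SNP-year changes beyond the replicate max, and
#'   the fraction of bins whose observed mean lies above the drift mean).
#' @export
compareToDrift <- function(observed, env) {
  stopifnot(all(c("line", "marker", "year", "absDp", "baselineMaf")
                %in% names(observed)))
  tab <- env@table
  perSnp <- observed
  perSnp$bin <- NA_character_
  perSnp$quantile <- NA_real_
  perSnp$exceedsMax <- NA
  perSnp$nearestBin <- FALSE
  for (ln in unique(observed$line)) {
    if (!ln %in% names(env@samples))
      stop("envelope has no line ", ln)
    bt <- unique(tab[tab$line == ln, c("bin", "binLow", "binHigh")])
    oi <- which(perSnp$line == ln)
    maf <- perSnp$baselineMaf[oi]
    k <- vapply(maf, function(m) {
      j <- which(m > bt$binLow - 1e-12 & m <= bt$binHigh + 1e-12)[1]
      if (is.na(j)) { # nearest bin
        j <- which.min(pmin(abs(m - bt$binLow), abs(m - bt$binHigh)))
        -j
      } else j
    }, numeric(1))
    perSnp$nearestBin[oi] <- k < 0
    k <- abs(k)
    perSnp$bin[oi] <- bt$bin[k]
    for (r in seq_along(oi)) {
      smp <- env@samples[[ln]][[bt$bin[k[r]]]][[
        as.character(perSnp$year[oi[r]])]]
      if (is.null(smp)) next
      x <- perSnp$absDp[oi[r]]
      perSnp$quantile[oi[r]] <- mean(smp <= x)
      perSnp$exceedsMax[oi[r]] <- x > max(smp)
    }
  }
  # per-bin z test of the mean
  key <- interaction(perSnp$line, perSnp$bin, perSnp$year, drop = TRUE)
  perBin <- do.call(rbind, lapply(split(perSnp, key), function(d) {
    smp <- env@samples[[d$line[1]]][[d$bin[1]]][[as.character(d$year[1])]]
    if (is.null(smp)) return(NULL)
    mO <- mean(d$absDp); mD <- mean(smp)
    se <- sqrt(stats::var(smp) / length(smp) +
                 stats::var(d$absDp) / max(nrow(d), 1))
    z <- if (nrow(d) > 1 && se > 0) (mO - mD) / se else NA_real_
    data.frame(line = d$line[1], bin = d$bin[1], year = d$year[1],
               nSnp = nrow(d), meanObs = mO, meanDrift = mD, z = z,
               p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  }))
  rownames(perBin) <- NULL
  list(perSnp = perSnp, perBin = perBin,
       summary = list(
         fracExceedsMax = mean(perSnp$exceedsMax, na.rm = TRUE),
         fracBinsMeanAboveDrift = mean(perBin$meanObs > perBin$meanDrift,
                                       na.rm = TRUE)))
}

#' Write a drift envelope as TSV
#'
#' @param env a [DriftEnvelope-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnvelope <- function(env, path) {
  utils::write.table(env@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
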