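#' Construct a GenotypeData container
#'
#' @param dosages numeric matrix, animals in rows (rownames = animal ids)
#'   and markers in columns (colnames = marker ids); values in \{0, 1, 2\}
#'   or `NA`.
#' @param map optional data.frame with columns `marker`, `chrom`, `pos`
#'   (1-based bp). Markers are sorted by (chrom, pos). Without a map all
#'   markers go on chromosome `"1"` at consecutive positions.
#' @param counted per-marker label of the counted allele (default `"ALT"`),
#'   the orientation metadata used when lines are compared.
#' @param animalInfo optional data.frame of per-animal columns (one row per
#'   animal, matching `rownames(dosages)`).
#' @return a [GenotypeData-class].
#' @export
GenotypeData <- function(dosages, map = NULL, counted = "ALT",
                         animalInfo = NULL) {
  stopifnot(is.matrix(dosages), !is.null(rownames(dosages)),
            !is.null(colnames(dosages)))
  markers <- colnames(dosages)
  if (is.null(map)) {
    map <- data.frame(marker = markers, chrom = "1",
                      pos = seq_along(markers), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("marker", "chrom", "pos") %in% names(map)))
  map <- map[match(markers, map$marker), , drop = FALSE]
  if (anyNA(map$marker)) stop("marker map does not cover all markers")
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  dosages <- dosages[, map$marker, drop = FALSE]
  counted <- rep_len(counted, nrow(map))
  rd <- S4Vectors::DataFrame(chrom = as.character(map$chrom),
                             pos = as.integer(map$pos), counted = counted,
                             row.names = map$marker)
  cd <- if (is.null(animalInfo)) {
    S4Vectors::DataFrame(row.names = rownames(dosages))
  } else {
    S4Vectors::DataFrame(animalInfo, row.names = rownames(dosages))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dosages)), rowData = rd, colData = cd)
  methods::new("GenotypeData", se)
}

#' Read SNP genotypes
#'
#' Supported formats: a dosage TSV (header row of marker ids, one row per
#' animal, first column the animal id, cells in \{0, 1, 2, NA\}), a VCF
#' (biallelic SNP records; dosage = ALT-allele count; multiallelic records
#' are skipped with a warning), and the PLINK `.raw` additive dialect.
#'
#' @param path genotype file.
#' @param format one of `"tsv"`, `"vcf"`, `"raw"`.
#' @param mapPath optional marker-map TSV (columns `marker`, `chrom`,
#'   `pos`) for the tsv/raw formats; VCF carries its own map.
#' @return a [GenotypeData-class] with markers sorted by (chrom, pos).
#' @export
readGenotypes <- function(path, format = c("tsv", "vcf", "raw"),
                          mapPath = NULL) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  map <- if (!is.null(mapPath)) {
    utils::read.table(mapPath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else NULL
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    M <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(M)) {
      bad <- which(apply(tab[, -1, drop = FALSE], 1,
                         function(r) any(!r %in% c("0", "1", "2", "NA", NA))))
      stop("malformed dosage row at line ", bad[1] + 1L)
    }
    if (any(!is.na(M) & !M %in% 0:2))
      stop("malformed dosage row at line ",
           which(rowSums(!is.na(M) & !(M %in% 0:2)) > 0)[1] + 1L)
    rownames(M) <- as.character(tab[[1]])
    return(GenotypeData(M, map = map))
  }
  if (format == "raw") {
    tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    fixed <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                       names(tab))
    M <- as.matrix(tab[, setdiff(names(tab), fixed), drop = FALSE])
    rownames(M) <- as.character(tab$IID)
    # PLINK suffixes the counted allele: snp_A -> marker "snp", counted "A"
    counted <- sub("^.*_", "", colnames(M))
    colnames(M) <- sub("_[^_]*$", "", colnames(M))
    return(GenotypeData(M, map = map, counted = counted))
  }
  # VCF via vcfR
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- function(g) {
    g[g %in% c("./.", ".|.", ".")] <- NA
    a <- strsplit(g, "[/|]")
    vapply(a, function(z) if (anyNA(z) || length(z) == 0) NA_real_
           else sum(z != "0"), numeric(1))
  }
  D <- apply(gt, 2, alt)                  # markers x animals
  if (is.null(dim(D))) D <- matrix(D, nrow = nrow(gt), dimnames = dimnames(gt))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  map <- data.frame(marker = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
  M <- t(D)
  colnames(M) <- ids
  GenotypeData(M, map = map, counted = fix[, "ALT"])
}

#' Write genotypes as a dosage TSV (plus marker map)
#'
#' Round-trips losslessly through [readGenotypes()] with `format = "tsv"`.
#'
#' @param geno a [GenotypeData-class].
#' @param path output TSV path.
#' @param mapPath optional path for the marker-map TSV.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(geno, path, mapPath = NULL) {
  M <- dosages(geno)
  df <- data.frame(animal = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(mapPath)) {
    utils::write.table(markerInfo(geno)[, c("marker", "chrom", "pos")],
                       mapPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Genotype quality control
#'
#' Applies, in this fixed order: (1) remove animals with a missing-call
#' fraction strictly above `animalMissMax`; (2) remove exact-duplicate
#' genotypes (identical calls including the missing pattern; the animal
#' with the lexicographically smallest id is kept); (3) remove animals
#' whose opposing-homozygote rate against a genotyped parent exceeds
#' `mendelConflictMax` (max over parents); (4) remove markers with a
#' missing fraction strictly above `markerMissMax`; (5) remove
#' monomorphic markers (all non-missing dosages equal).
#'
#' @param geno a [GenotypeData-class].
#' @param ped optional [Pedigree-class]; required for the Mendelian
#'   conflict check (skipped when `NULL`).
#' @param animalMissMax,markerMissMax missingness thresholds in \[0, 1\].
#' @param mendelConflictMax opposing-homozygote rate threshold.
#' @param duplicateCheck run the duplicate stage (default `TRUE`).
#' @return list with elements `genotypes` (filtered [GenotypeData-class])
#'   and `report` (list: `animalsRemoved`, `markersRemoved` data.frames
#'   with reasons, and the thresholds used).
#' @export
qcGenotypes <- function(geno, ped = NULL, animalMissMax = 0.05,
                        markerMissMax = 0.05, mendelConflictMax = 0.02,
                        duplicateCheck = TRUE) {
  stopifnot(animalMissMax >= 0, animalMissMax <= 1,
            markerMissMax >= 0, markerMissMax <= 1,
            mendelConflictMax >= 0, mendelConflictMax <= 1)
  M <- dosages(geno)
  aRem <- data.frame(id = character(0), reason = character(0),
                     value = numeric(0), stringsAsFactors = FALSE)
  # (1) animal missingness
  miss <- rowMeans(is.na(M))
  drop1 <- miss > animalMissMax
  if (any(drop1))
    aRem <- rbind(aRem, data.frame(id = rownames(M)[drop1],
                                   reason = "missingness",
                                   value = miss[drop1]))
  M <- M[!drop1, , drop = FALSE]
  # (2) exact duplicates, keep smallest id
  if (duplicateCheck && nrow(M) > 1) {
    ordIds <- order(rownames(M))
    key <- apply(M[ordIds, , drop = FALSE], 1, paste, collapse = ",")
    dup <- duplicated(key)
    if (any(dup)) {
      dupIds <- rownames(M)[ordIds][dup]
      aRem <- rbind(aRem, data.frame(id = dupIds, reason = "duplicate",
                                     value = NA_real_))
      M <- M[!rownames(M) %in% dupIds, , drop = FALSE]
    }
  }
  # (3) pedigree-genotype conflict (opposing homozygotes vs genotyped parent)
  if (!is.null(ped)) {
    rec <- ped@records
    rows <- match(rownames(M), rec$id)
    rate <- rep(NA_real_, nrow(M))
    for (k in seq_len(nrow(M))) {
      if (is.na(rows[k])) next
      worst <- NA_real_
      for (p in c(rec$sire[rows[k]], rec$dam[rows[k]])) {
        if (is.na(p) || !p %in% rownames(M)) next
        a <- M[k, ]; b <- M[p, ]
        ok <- !is.na(a) & !is.na(b)
        if (!any(ok)) next
        r <- mean(abs(a[ok] - b[ok]) == 2)
        worst <- max(worst, r, na.rm = TRUE)
      }
      rate[k] <- worst
    }
    drop3 <- !is.na(rate) & rate > mendelConflictMax
    if (any(drop3)) {
      aRem <- rbind(aRem, data.frame(id = rownames(M)[drop3],
                                     reason = "pedigree_conflict",
                                     value = rate[drop3]))
      M <- M[!drop3, , drop = FALSE]
    }
  }
  # (4) marker missingness
  mRem <- data.frame(marker = character(0), reason = character(0),
                     value = numeric(0), stringsAsFactors = FALSE)
  mmiss <- colMeans(is.na(M))
  drop4 <- mmiss > markerMissMax
  if (any(drop4))
    mRem <- rbind(mRem, data.frame(marker = colnames(M)[drop4],
                                   reason = "missingness",
                                   value = mmiss[drop4]))
  M <- M[, !drop4, drop = FALSE]
  # (5) monomorphic markers
  mono <- apply(M, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0 || all(x == x[1])
  })
  if (any(mono))
    mRem <- rbind(mRem, data.frame(marker = colnames(M)[mono],
                                   reason = "monomorphic",
                                   value = NA_real_))
  M <- M[, !mono, drop = FALSE]
  if (nrow(M) == 0 || ncol(M) == 0)
    stop("QC removed all ", if (nrow(M) == 0) "animals" else "markers")
  info <- markerInfo(geno)
  out <- GenotypeData(M, map = info[info$marker %in% colnames(M),
                                    c("marker", "chrom", "pos")],
                      counted = info$counted[match(colnames(M), info$marker)])
  rownames(aRem) <- rownames(mRem) <- NULL
  list(genotypes = out,
       report = list(animalsRemoved = aRem, markersRemoved = mRem,
                     thresholds = list(animalMissMax = animalMissMax,
                                       markerMissMax = markerMissMax,
                                       mendelConflictMax = mendelConflictMax)))
}

#' Mean-impute residual missing genotypes
#'
#' Replaces each missing call by the marker's mean dosage over non-missing
#' calls (a real number, not rounded). Non-missing cells are untouched.
#'
#' @param geno a [GenotypeData-class]; every marker needs at least one
#'   non-missing call (run [qcGenotypes()] first).
#' @return a complete [GenotypeData-class].
#' @export
imputeMean <- function(geno) {
  M <- dosages(geno)
  mu <- colMeans(M, na.rm = TRUE)
  if (anyNA(mu)) stop("all-missing marker(s): ",
                      paste(utils::head(colnames(M)[is.na(mu)], 5),
                            collapse = ", "))
  idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(idx)) M[idx] <- mu[idx[, 2]]
  info <- markerInfo(geno)
  GenotypeData(M, map = info[, c("marker", "chrom", "pos")],
               counted = info$counted)
}

#' Allele frequencies per birth-year cohort
#'
#' p(line, year, marker) = sum of dosages / (2 x non-missing count) over
#' the cohort's animals.
#'
#' @param geno a [GenotypeData-class].
#' @param cohorts named list, calendar year -> animal ids.
#' @param line line label stored in the output.
#' @return AfTable: data.frame `line`, `year`, `marker`, `p`, `n`
#'   (non-missing animals), with the counted-allele labels attached as
#'   attribute `counted` (named by marker).
#' @export
alleleFreqByCohort <- function(geno, cohorts, line = "1") {
  M <- dosages(geno)
  keep <- vapply(cohorts, function(ids) length(intersect(ids, rownames(M))) > 0,
                 logical(1))
  if (any(!keep))
    warning("omitting empty cohort year(s): ",
            paste(names(cohorts)[!keep], collapse = ", "))
  cohorts <- cohorts[keep]
  if (!length(cohorts)) stop("no non-empty cohorts")
  res <- lapply(names(cohorts), function(y) {
    ids <- intersect(cohorts[[y]], rownames(M))
    B <- M[ids, , drop = FALSE]
    n <- colSums(!is.na(B))
    p <- colSums(B, na.rm = TRUE) / (2 * n)
    data.frame(line = line, year = as.numeric(y), marker = colnames(M),
               p = as.numeric(p), n = as.integer(n),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  info <- markerInfo(geno)
  attr(out, "counted") <- stats::setNames(info$counted, info$marker)
  out
}

#' Genotyped birth-year cohorts from a pedigree
#'
#' @param ped a [Pedigree-class].
#' @param line optional line label filter.
#' @param years optional calendar years to keep.
#' @return named list, year -> genotyped animal ids born that year.
#' @export
cohortList <- function(ped, line = NULL, years = NULL) {
  rec <- ped@records
  keep <- rec$genotyped & !is.na(rec$birth)
  if (!is.null(line)) keep <- keep & !is.na(rec$line) & rec$line == line
  yr <- floor(rec$birth)
  if (is.null(years)) years <- sort(unique(yr[keep]))
  out <- lapply(years, function(y) rec$id[keep & yr == y])
  stats::setNames(out, years)
}
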