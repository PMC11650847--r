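#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats lm coef optimize optim rnorm runif rbinom pnorm pt
#'   qchisq median quantile var sd setNames complete.cases ks.test aggregate
#' @importFrom utils read.table write.table head
#' @useDynLib seldrift, .registration = TRUE
NULL

#' Pedigree of a closed breeding population
#'
#' Holds one validated pedigree in topological order (every known parent
#' precedes its offspring). Records carry a birth time in decimal years, a
#' sex code, a line label and a genotyped flag; unknown parents are `NA`.
#' Build objects with [readPedigree()] or [asPedigree()].
#'
#' @slot records data.frame with columns `id`, `sire`, `dam`, `birth`,
#'   `sex`, `line`, `genotyped`, topologically sorted.
#' @slot autoAdded character, ids that appeared only as parents and were
#'   added as founder records with unknown birth time.
#' @export
setClass("Pedigree",
         representation(records = "data.frame", autoAdded = "character"))

setValidity("Pedigree", function(object) {
  rec <- object@records
  need <- c("id", "sire", "dam", "birth", "sex", "line", "genotyped")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(rec$id)) return("duplicate animal ids")
  pos <- seq_len(nrow(rec))
  names(pos) <- rec$id
  for (col in c("sire", "dam")) {
    p <- rec[[col]]
    known <- !is.na(p)
    if (any(!p[known] %in% rec$id))
      return(sprintf("unknown %s id referenced", col))
    if (any(pos[p[known]] >= pos[known]))
      return("pedigree not topologically ordered (parent after offspring)")
  }
  TRUE
})

#' Genotype dosage container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with markers as rows and
#' animals as columns. The single assay `"dosage"` holds counted-allele
#' dosages in \{0, 1, 2\} (`NA` = missing call; after mean imputation the
#' values are real numbers in \[0, 2\]). `rowData` carries the marker map
#' (`chrom`, `pos`, and `counted` allele label).
#'
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' missing")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chrom", "pos") %in% colnames(rd)))
    return("rowData must have columns 'chrom' and 'pos'")
  d <- SummarizedExperiment::assay(object, "dosage")
  rng <- range(d, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    return("dosages outside [0, 2]")
  TRUE
})

#' Effective population size estimate
#'
#' Result of [estimateNe()]: the regression of log(1 - f_t) on calendar
#' year, converted to a rate of inbreeding per year, per generation, and an
#' effective population size Ne = 1 / (2 dF_gen).
#'
#' @slot slope regression coefficient of log(1 - f_t) on year.
#' @slot deltaFYear rate of inbreeding per year, 1 - exp(slope).
#' @slot generationInterval L, mean parent age at offspring birth (years).
#' @slot deltaFGen rate of inbreeding per generation, L * deltaFYear.
#' @slot ne effective population size (NA when dF_gen <= 0).
#' @slot neDisplay ne rounded half-to-even for display.
#' @slot defined FALSE when kinship is non-increasing so Ne is undefined.
#' @slot nYears number of cohort points used in the regression.
#' @slot series the kinship-by-year series used (data.frame year, f, nPairs).
#' @export
setClass("NeEstimate",
         representation(slope = "numeric", deltaFYear = "numeric",
                        generationInterval = "numeric", deltaFGen = "numeric",
                        ne = "numeric", neDisplay = "numeric",
                        defined = "logical", nYears = "integer",
                        series = "data.frame"))

#' Genomic relationship matrix (VanRaden method 1)
#'
#' @slot matrix symmetric realized-relationship matrix over animals.
#' @slot denom scaling denominator 2 * sum p(1-p).
#' @slot freqs per-marker counted-allele frequencies used for centering.
#' @slot freqSource "data" when frequencies came from the analyzed animals,
#'   else "user".
#' @export
setClass("Grm",
         representation(matrix = "matrix", denom = "numeric",
                        freqs = "numeric", freqSource = "character"))

#' Variance components of the null mixed model
#'
#' REML estimates for y = Xb + Z1 u + Z2 a + e with a ~ N(0, G sigma2_A),
#' u i.i.d. per extra random factor, e ~ N(0, I sigma2_E).
#'
#' @slot sigmaA additive genetic variance.
#' @slot sigmaE residual variance.
#' @slot extra named numeric, variances of extra random factors.
#' @slot h2 sigmaA / total variance.
#' @slot logLik restricted log-likelihood at the optimum (up to a constant).
#' @slot converged logical.
#' @slot boundary TRUE when a variance was pinned at the zero boundary.
#' @slot method "eigen-profile" or "direct-reml".
#' @export
setClass("VarianceComponents",
         representation(sigmaA = "numeric", sigmaE = "numeric",
                        extra = "numeric", h2 = "numeric", logLik = "numeric",
                        converged = "logical", boundary = "logical",
                        method = "character"))

#' Gene-dropping trajectories
#'
#' Per founder-MAF grid value, cohort allele frequencies for every replicate
#' of a single-locus Mendelian drop through the pedigree.
#'
#' @slot maf founder MAF grid.
#' @slot freq list (one per grid value) of cohort x replicate frequency
#'   matrices.
#' @slot cohorts data.frame line, year, n (cohort sizes; rows match the
#'   frequency matrices).
#' @slot nrep replicates per grid value.
#' @slot seed root seed used.
#' @export
setClass("DriftTrajectories",
         representation(maf = "numeric", freq = "list", cohorts = "data.frame",
                        nrep = "integer", seed = "integer"))

#' Drift envelope: allele-frequency change under pure drift
#'
#' Summaries of |dp| between a baseline cohort and later cohorts, binned by
#' the replicate's realized baseline-cohort MAF.
#'
#' @slot table data.frame line, bin, binLow, binHigh, year, n, meanAbsDp,
#'   ciLow, ciHigh, q95, q99, maxAbsDp, merged.
#' @slot samples nested list line -> bin label -> year -> numeric |dp|
#'   replicates (kept so observed SNPs can be placed at a quantile).
#' @slot baselineYear baseline calendar year.
#' @slot binWidth MAF bin width.
#' @slot nFixed replicates fixed (p in \{0,1\}) in the baseline cohort,
#'   excluded from the bins, per line.
#' @export
setClass("DriftEnvelope",
         representation(table = "data.frame", samples = "list",
                        baselineYear = "numeric", binWidth = "numeric",
                        nFixed = "numeric"))

setMethod("show", "Pedigree", function(object) {
  rec <- object@records
  cat(sprintf("Pedigree: %d animals (%d founders, %d genotyped)\n",
              nrow(rec), sum(is.na(rec$sire) & is.na(rec$dam)),
              sum(rec$genotyped)))
  yrs <- range(rec$birth, na.rm = TRUE)
  if (all(is.finite(yrs)))
    cat(sprintf("  birth years %.1f-%.1f; lines: %s\n", yrs[1], yrs[2],
                paste(unique(rec$line), collapse = ", ")))
  if (length(object@autoAdded))
    cat(sprintf("  %d parent-only ids auto-added as founders\n",
                length(object@autoAdded)))
})

setMethod("show", "NeEstimate", function(object) {
  cat("Effective population size estimate\n")
  cat(sprintf("  slope b of ln(1 - f_t) on year : %.6f (%d years)\n",
              object@slope, object@nYears))
  cat(sprintf("  dF/year = %.5f, L = %.2f, dF/generation = %.5f\n",
              object@deltaFYear, object@generationInterval, object@deltaFGen))
  if (object@defined)
    cat(sprintf("  Ne = %.2f (display %d)\n", object@ne,
                as.integer(object@neDisplay)))
  else cat("  Ne undefined (kinship non-increasing)\n")
})

setMethod("show", "Grm", function(object) {
  cat(sprintf("GRM (VanRaden method 1): %d animals, denom 2*sum p(1-p) = %.3f, freqs from %s\n",
              nrow(object@matrix), object@denom, object@freqSource))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("Variance components (%s): sigma2_A = %.4f, sigma2_E = %.4f",
              object@method, object@sigmaA, object@sigmaE))
  if (length(object@extra))
    cat(", ", paste(sprintf("%s = %.4f", names(object@extra), object@extra),
                    collapse = ", "), sep = "")
  cat(sprintf("; h2 = %.3f%s\n", object@h2,
              if (object@boundary) " [boundary]" else ""))
})

setMethod("show", "DriftTrajectories", function(object) {
  cat(sprintf("Gene-dropping trajectories: %d MAF values x %d replicates over %d cohorts\n",
              length(object@maf), object@nrep, nrow(object@cohorts)))
})

setMethod("show", "DriftEnvelope", function(object) {
  cat(sprintf("Drift envelope vs baseline %s: %d (line, bin, year) cells, bin width %.2f\n",
              format(object@baselineYear), nrow(object@table), object@binWidth))
})
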