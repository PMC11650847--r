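#' Allele-frequency change versus a baseline year
#'
#' Per line, marker and year: the signed and absolute change relative to
#' the baseline-year cohort frequency, plus the baseline MAF (folded to
#' <= 0.5). Markers absent from the baseline year are dropped with a
#' warning.
#'
#' @param af AfTable from [alleleFreqByCohort()] (one or more lines
#'   row-bound; the `counted` attribute is propagated).
#' @param baselineYear baseline calendar year.
#' @return AfChangeTable: data.frame `line`, `marker`, `year`, `p`,
#'   `pBaseline`, `dp`, `absDp`, `baselineMaf`.
#' @export
absChangeVsBaseline <- function(af, baselineYear) {
  stopifnot(all(c("line", "year", "marker", "p") %in% names(af)))
  out <- lapply(split(af, af$line), function(d) {
    base <- d[d$year == baselineYear, ]
    if (!nrow(base)) stop("baseline year ", baselineYear,
                          " absent for line ", d$line[1])
    p0 <- stats::setNames(base$p, base$marker)
    drop <- !d$marker %in% names(p0)
    if (any(drop)) {
      warning(sum(drop), " marker-year rows without baseline dropped")
      d <- d[!drop, ]
    }
    pb <- p0[d$marker]
    data.frame(line = d$line, marker = d$marker, year = d$year, p = d$p,
               pBaseline = as.numeric(pb), dp = d$p - pb,
               absDp = abs(d$p - pb), baselineMaf = pmin(pb, 1 - pb),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "counted") <- attr(af, "counted")
  attr(res, "baselineYear") <- baselineYear
  res
}

#' MAF-stratified summary of allele-frequency changes
#'
#' Strata are right-closed intervals of baseline MAF (default (0, 0.05],
#' (0.05, 0.1], (0.1, 0.2], (0.2, 0.5]; a marker at exactly 0.05 falls in
#' the first stratum). Per (line, stratum, horizon year): count, max |dp|
#' and quantiles. Empty strata are reported with count 0.
#'
#' @param chg AfChangeTable from [absChangeVsBaseline()].
#' @param breaks stratum edges (default `c(0, 0.05, 0.1, 0.2, 0.5)`).
#' @param quantiles quantile levels reported (default 0.5, 0.95, 0.99).
#' @return data.frame `line`, `stratum`, `year`, `n`, `maxAbsDp` and one
#'   column per quantile.
#' @export
mafStratifiedSummary <- function(chg, breaks = c(0, 0.05, 0.1, 0.2, 0.5),
                                 quantiles = c(0.5, 0.95, 0.99)) {
  labs <- sprintf("(%g,%g]", breaks[-length(breaks)], breaks[-1])
  chg$stratum <- cut(chg$baselineMaf, breaks = breaks, labels = labs,
                     right = TRUE)
  grid <- expand.grid(line = unique(chg$line), stratum = labs,
                      year = sort(unique(chg$year)),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- chg[chg$line == grid$line[i] &
               !is.na(chg$stratum) & chg$stratum == grid$stratum[i] &
               chg$year == grid$year[i], ]
    q <- if (nrow(d)) stats::quantile(d$absDp, quantiles, names = FALSE)
         else rep(NA_real_, length(quantiles))
    cbind(grid[i, , drop = FALSE],
          data.frame(n = nrow(d),
                     maxAbsDp = if (nrow(d)) max(d$absDp) else NA_real_,
                     t(stats::setNames(q, paste0("q", quantiles * 100)))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regression of allele-frequency change on GWAS effect and significance
#'
#' Ordinary least squares of the year-to-next-year |dp| on the absolute
#' estimated allele substitution effect and, separately, on -log10 p from
#' the same year's scan (a signed-on-signed option is available). This is
#' the per-year "is frequency change predicted by the association result"
#' diagnostic; under pure drift both slopes and R-squared are near zero.
#'
#' @param chg AfChangeTable restricted to a single horizon (the changes
#'   from the scan year to the next year).
#' @param res GwasResult data.frame for the scan year.
#' @param mafMin exclude markers with analysis-set MAF below this (uses
#'   `res$maf`; default 0 = keep all).
#' @param signed regress signed dp on the signed effect instead.
#' @return data.frame with one row per predictor (`absEffect`,
#'   `neglog10p`): `slope`, `r2`, `n`, `degenerate` (TRUE when the
#'   predictor has zero variance).
#' @export
changeVsGwasRegression <- function(chg, res, mafMin = 0, signed = FALSE) {
  if (length(unique(chg$year)) != 1)
    stop("chg must hold a single horizon year")
  keep <- !is.na(res$effect) & res$maf >= mafMin
  d <- merge(chg, res[keep, c("marker", "effect", "neglog10p")],
             by = "marker")
  if (nrow(d) < 3) stop("fewer than 3 shared markers")
  yv <- if (signed) d$dp else d$absDp
  one <- function(xv, nm) {
    if (stats::var(xv) == 0)
      return(data.frame(predictor = nm, slope = NA_real_, r2 = NA_real_,
                        n = nrow(d), degenerate = TRUE))
    fit <- stats::lm(yv ~ xv)
    data.frame(predictor = nm, slope = unname(stats::coef(fit)[2]),
               r2 = summary(fit)$r.squared, n = nrow(d), degenerate = FALSE)
  }
  out <- rbind(one(if (signed) d$effect else abs(d$effect), "absEffect"),
               one(d$neglog10p, "neglog10p"))
  if (signed) out$predictor[1] <- "effect"
  rownames(out) <- NULL
  attr(out, "mafMin") <- mafMin
  attr(out, "signed") <- signed
  out
}

#' Squared correlation of allele-frequency changes between two lines
#'
#' Pearson correlation of signed dp over the shared markers at one
#' horizon, squared. Requires the counted-allele orientation metadata on
#' both tables (a silent flip would corrupt the sign).
#'
#' @param chgA,chgB AfChangeTables from [absChangeVsBaseline()], one line
#'   each.
#' @param year horizon calendar year.
#' @return R-squared, with attribute `n` (shared markers).
#' @export
betweenLineCorrelation <- function(chgA, chgB, year) {
  cA <- attr(chgA, "counted"); cB <- attr(chgB, "counted")
  if (is.null(cA) || is.null(cB))
    stop("counted-allele orientation metadata missing")
  a <- chgA[chgA$year == year, ]
  b <- chgB[chgB$year == year, ]
  shared <- intersect(a$marker, b$marker)
  if (!length(shared)) stop("no shared markers")
  if (!identical(unname(cA[shared]), unname(cB[shared])))
    stop("counted alleles differ between lines for shared markers")
  r <- stats::cor(a$dp[match(shared, a$marker)],
                  b$dp[match(shared, b$marker)])
  structure(r^2, n = length(shared))
}

#' Minor-allele-oriented trajectories of significant SNPs in a region
#'
#' Selects the markers in a chromosome window whose -log10 p meets the
#' threshold and returns their yearly cohort frequencies oriented to the
#' allele that was minor (frequency < 0.5) in the baseline year; at
#' exactly 0.5 the counted allele is kept. The lead SNP is the most
#' significant one, ties broken by smaller position.
#'
#' @param af AfTable for one line.
#' @param res GwasResult data.frame.
#' @param chrom chromosome label of the region.
#' @param start,end 1-based position window.
#' @param threshold -log10 p significance threshold.
#' @param baselineYear year whose minor allele is tracked.
#' @return data.frame `marker`, `chrom`, `pos`, `year`, `p` (oriented),
#'   `neglog10p`, `flipped`, `lead`.
#' @export
trajectoryOfSignificant <- function(af, res, chrom, start, end, threshold,
                                    baselineYear) {
  inReg <- res$chrom == chrom & res$pos >= start & res$pos <= end
  sig <- inReg & !is.na(res$neglog10p) & res$neglog10p >= threshold
  if (!any(inReg)) stop("empty region")
  if (!any(sig)) stop("no marker above threshold in region")
  sel <- res[sig, c("marker", "chrom", "pos", "neglog10p")]
  d <- af[af$marker %in% sel$marker, c("marker", "year", "p")]
  base <- d[d$year == baselineYear, ]
  p0 <- stats::setNames(base$p, base$marker)
  flip <- p0 > 0.5
  d$flipped <- unname(flip[d$marker])
  d$p <- ifelse(d$flipped, 1 - d$p, d$p)
  d <- merge(d, sel, by = "marker")
  ord <- order(-sel$neglog10p, sel$pos)
  leadMarker <- sel$marker[ord[1]]
  d$lead <- d$marker == leadMarker
  d <- d[order(d$marker, d$year),
         c("marker", "chrom", "pos", "year", "p", "neglog10p", "flipped",
           "lead")]
  rownames(d) <- NULL
  d
}
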