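#' Genomic relationship matrix, VanRaden method 1
#'
#' G = Z Z' / (2 sum p(1-p)) with Z = M - 2P, where M is the (complete)
#' animals x markers dosage matrix and P the row-replicated counted-allele
#' frequencies. When frequencies are computed from the analyzed animals
#' themselves the grand sum of G is 0 (columns of Z sum to zero).
#'
#' @param geno a complete [GenotypeData-class] (no missing dosages; run
#'   [imputeMean()] first).
#' @param freqs optional per-marker frequencies for centering; default:
#'   computed from the data (mean dosage / 2). Markers monomorphic under
#'   the frequencies used are an error.
#' @return a [Grm-class].
#' @export
computeGrm <- function(geno, freqs = NULL) {
  M <- dosages(geno)
  if (anyNA(M)) stop("missing dosages; impute first")
  fromData <- is.null(freqs)
  if (fromData) freqs <- colMeans(M) / 2
  if (length(freqs) != ncol(M)) stop("freqs length mismatch")
  mono <- freqs <= 0 | freqs >= 1
  if (any(mono))
    stop("monomorphic marker(s) passed to GRM: ",
         paste(utils::head(colnames(M)[mono], 5), collapse = ", "))
  Z <- sweep(M, 2, 2 * freqs)
  denom <- 2 * sum(freqs * (1 - freqs))
  G <- tcrossprod(Z) / denom
  methods::new("Grm", matrix = G, denom = denom,
               freqs = stats::setNames(freqs, colnames(M)),
               freqSource = if (fromData) "data" else "user")
}

#' Assemble a single-trait GWAS design
#'
#' Builds the response and incidence structures for the mixed model
#' y = X b + Z1 u + Z2 a + w v + e: fixed-effect design matrix X (mean plus
#' the named fixed factors), one incidence matrix per extra random factor,
#' and the animal id per record (which maps records to GRM rows). Records
#' with a missing response or missing factor level are dropped; factor
#' levels with zero observations are dropped.
#'
#' @param pheno data.frame of phenotypes and factor columns.
#' @param trait response column name.
#' @param fixed character vector of fixed-factor column names (an
#'   intercept is always included).
#' @param random character vector of extra random-factor column names
#'   (besides the animal genomic effect).
#' @param idCol animal id column (default `"animal"`).
#' @return list of class `GwasDesign`: `y`, `X`, `Z` (named list of
#'   incidence matrices), `animal`, `trait`.
#' @export
gwasDesign <- function(pheno, trait, fixed = character(),
                       random = character(), idCol = "animal") {
  stopifnot(trait %in% names(pheno), idCol %in% names(pheno),
            all(fixed %in% names(pheno)), all(random %in% names(pheno)))
  use <- stats::complete.cases(pheno[, c(trait, fixed, random, idCol),
                                     drop = FALSE])
  d <- pheno[use, , drop = FALSE]
  y <- as.numeric(d[[trait]])
  if (length(y) < 2 || !isTRUE(stats::var(y) > 0))
    stop("response '", trait, "' has zero variance")
  X <- if (length(fixed)) {
    for (f in fixed) d[[f]] <- droplevels(factor(d[[f]]))
    stats::model.matrix(stats::reformulate(fixed), data = d)
  } else matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  Z <- lapply(stats::setNames(random, random), function(f) {
    v <- droplevels(factor(d[[f]]))
    stats::model.matrix(~ 0 + v)
  })
  structure(list(y = y, X = X, Z = Z, animal = as.character(d[[idCol]]),
                 trait = trait, fixed = fixed, random = random),
            class = "GwasDesign")
}

# phenotypic covariance V implied by the components, over design records
buildV <- function(design, grm, vc) {
  G <- grmMatrix(grm)
  miss <- setdiff(design$animal, rownames(G))
  if (length(miss)) stop("animal(s) missing from GRM: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  Gs <- G[design$animal, design$animal]
  n <- length(design$y)
  V <- vc@sigmaA * Gs + diag(vc@sigmaE, n)
  for (nm in names(design$Z))
    V <- V + vc@extra[[nm]] * tcrossprod(design$Z[[nm]])
  V
}

#' REML variance components of the null model
#'
#' Restricted maximum likelihood for y = X b + Z1 u + Z2 a + e with
#' a ~ N(0, G sigma2_A) and i.i.d. extra random factors. Models with only
#' the animal effect are solved by eigendecomposition of the (subset) GRM
#' and one-dimensional profile-REML optimization of the variance ratio;
#' models with extra random factors maximize the restricted likelihood
#' directly (Cholesky evaluation, L-BFGS-B on log variances). Convergence
#' tolerance: successive restricted log-likelihoods within 1e-8.
#'
#' @param design a [gwasDesign()].
#' @param grm a [Grm-class] covering all phenotyped animals.
#' @return a [VarianceComponents-class]; a variance pinned at the zero
#'   boundary is flagged, not an error.
#' @export
remlNull <- function(design, grm) {
  stopifnot(inherits(design, "GwasDesign"))
  y <- design$y; X <- design$X
  n <- length(y); p <- ncol(X)
  G <- grmMatrix(grm)
  miss <- setdiff(design$animal, rownames(G))
  if (length(miss)) stop("animal(s) missing from GRM: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  Gs <- G[design$animal, design$animal]
  if (length(design$Z) == 0) {
    e <- eigen(Gs, symmetric = TRUE)
    dv <- pmax(e$values, 0)
    ys <- crossprod(e$vectors, y)
    Xs <- crossprod(e$vectors, X)
    profLl <- function(lg) {
      g <- exp(lg)
      w <- g * dv + 1
      Xw <- Xs / w
      XtX <- crossprod(Xs, Xw)
      bhat <- solve(XtX, crossprod(Xw, ys))
      r <- ys - Xs %*% bhat
      rss <- sum(r^2 / w)
      sigE <- rss / (n - p)
      -0.5 * ((n - p) * log(sigE) + sum(log(w)) +
                determinant(XtX, logarithm = TRUE)$modulus + (n - p))
    }
    opt <- stats::optimize(profLl, c(-20, 20), maximum = TRUE, tol = 1e-9)
    g <- exp(opt$maximum)
    w <- g * dv + 1
    Xw <- Xs / w
    bhat <- solve(crossprod(Xs, Xw), crossprod(Xw, ys))
    sigE <- sum((ys - Xs %*% bhat)^2 / w) / (n - p)
    sigA <- g * sigE
    boundary <- opt$maximum <= -20 + 1e-6 || opt$maximum >= 20 - 1e-6
    return(methods::new("VarianceComponents", sigmaA = sigA, sigmaE = sigE,
                        extra = stats::setNames(numeric(0), character(0)),
                        h2 = sigA / (sigA + sigE),
                        logLik = as.numeric(opt$objective), converged = TRUE,
                        boundary = boundary, method = "eigen-profile"))
  }
  ZZ <- lapply(design$Z, tcrossprod)
  k <- length(ZZ)
  restLl <- function(theta) {
    s <- exp(theta)
    V <- s[1] * Gs + diag(s[k + 2], n)
    for (j in seq_len(k)) V <- V + s[j + 1] * ZZ[[j]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    Viy <- Vi %*% y
    Py <- Viy - ViX %*% solve(XtViX, crossprod(X, Viy))
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
                    determinant(XtViX, logarithm = TRUE)$modulus +
                    sum(y * Py))
    -as.numeric(ll)
  }
  v0 <- stats::var(y) / (k + 2)
  theta0 <- rep(log(v0), k + 2)
  opt <- stats::optim(theta0, restLl, method = "L-BFGS-B",
                      lower = log(v0) - 25, upper = log(v0) + 12,
                      control = list(maxit = 500, factr = 1e4))
  if (opt$convergence != 0)
    stop("REML did not converge (code ", opt$convergence, "); last = ",
         paste(signif(exp(opt$par), 4), collapse = ", "))
  s <- exp(opt$par)
  boundary <- any(opt$par <= log(v0) - 25 + 1e-6)
  extra <- stats::setNames(s[seq_len(k) + 1], names(design$Z))
  methods::new("VarianceComponents", sigmaA = s[1], sigmaE = s[k + 2],
               extra = extra, h2 = s[1] / sum(s),
               logLik = -opt$value, converged = TRUE, boundary = boundary,
               method = "direct-reml")
}

#' Single-SNP mixed-model scan with fixed variance components
#'
#' For each marker i fits y = X b + Z1 u + Z2 a + w_i v_i + e by
#' generalized least squares with V fixed from the null variance
#' components (the incidence matrices are shared across SNPs, so V and the
#' fixed-effect projection are factored once). Reports the allele
#' substitution effect v, its SE, the Wald statistic, p-value and the
#' variance explained 2p(1-p)v^2.
#'
#' @param design a [gwasDesign()].
#' @param grm a [Grm-class].
#' @param vc a [VarianceComponents-class] from [remlNull()] (held fixed;
#'   no per-SNP REML).
#' @param geno a complete [GenotypeData-class] containing all design
#'   animals.
#' @param test `"normal"` (Wald z against the standard normal, default)
#'   or `"t"` (residual-df t reference).
#' @return GwasResult data.frame: `marker`, `chrom`, `pos`, `maf`,
#'   `effect`, `se`, `z`, `p`, `neglog10p`, `varExplained`; markers
#'   collinear with the fixed effects get `NA` (not-estimable sentinel).
#'   Attributes: `trait`, `n`, `test`.
#' @export
snpScan <- function(design, grm, vc, geno, test = c("normal", "t")) {
  test <- match.arg(test)
  stopifnot(inherits(design, "GwasDesign"))
  y <- design$y; X <- design$X
  n <- length(y)
  Mall <- dosages(geno)
  miss <- setdiff(design$animal, rownames(Mall))
  if (length(miss)) stop("animal(s) missing from genotypes: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  W <- Mall[design$animal, , drop = FALSE]
  if (anyNA(W)) stop("missing dosages; impute first")
  V <- buildV(design, grm, vc)
  Vi <- chol2inv(chol(V))
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  XtViXi <- solve(XtViX)
  Viy <- Vi %*% y
  Py <- Viy - ViX %*% (XtViXi %*% crossprod(X, Viy))
  ViW <- Vi %*% W
  B <- crossprod(X, ViW)
  wPy <- as.numeric(crossprod(W, Py))
  wPw <- colSums(W * ViW) - colSums(B * (XtViXi %*% B))
  scale <- mean(colSums(W * ViW))
  est <- wPw > 1e-10 * max(scale, 1e-300)
  eff <- se <- z <- pv <- nl <- rep(NA_real_, ncol(W))
  eff[est] <- wPy[est] / wPw[est]
  se[est] <- 1 / sqrt(wPw[est])
  z[est] <- eff[est] / se[est]
  if (test == "normal") {
    lp <- stats::pnorm(-abs(z[est]), log.p = TRUE)
  } else {
    lp <- stats::pt(-abs(z[est]), df = n - ncol(X) - 1, log.p = TRUE)
  }
  pv[est] <- pmin(2 * exp(lp), 1)
  nl[est] <- -(log(2) + lp) / log(10)
  pbar <- colMeans(W) / 2
  maf <- pmin(pbar, 1 - pbar)
  info <- markerInfo(geno)
  res <- data.frame(marker = colnames(W),
                    chrom = info$chrom[match(colnames(W), info$marker)],
                    pos = info$pos[match(colnames(W), info$marker)],
                    maf = maf, effect = eff, se = se, z = z, p = pv,
                    neglog10p = nl,
                    varExplained = 2 * pbar * (1 - pbar) * eff^2,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "trait") <- design$trait
  attr(res, "n") <- n
  attr(res, "test") <- test
  res
}

#' Bonferroni genome-wide significance threshold
#'
#' Assuming the number of independent tests equals the number of SNPs,
#' returns -log10(alpha / nTests).
#'
#' @param alpha family-wise type-1 error rate, in (0, 1].
#' @param nTests number of tests (>= 1).
#' @return threshold on the -log10(p) scale.
#' @export
bonferroniThreshold <- function(alpha = 0.05, nTests) {
  stopifnot(alpha > 0, alpha <= 1, nTests >= 1)
  -log10(alpha / nTests)
}

#' Variance explained by one SNP
#'
#' 2 p (1 - p) v^2 with p the allele frequency and v the allele
#' substitution effect; optionally as a fraction of phenotypic variance.
#'
#' @param p allele frequency in \[0, 1\].
#' @param v allele substitution effect (trait units per counted-allele
#'   copy).
#' @param phenVar optional phenotypic variance to divide by.
#' @return variance in trait units squared (or a fraction).
#' @export
varianceExplained <- function(p, v, phenVar = NULL) {
  stopifnot(all(p >= 0 & p <= 1))
  out <- 2 * p * (1 - p) * v^2
  if (!is.null(phenVar)) out <- out / phenVar
  out
}

#' Genomic inflation factor and QQ table
#'
#' lambda_gc is the median Wald chi-square statistic divided by the
#' chi-square(1) median (0.4549364); the QQ table pairs sorted observed
#' -log10 p with the plotting positions -log10(k / (n + 1)).
#'
#' @param res GwasResult data.frame from [snpScan()].
#' @return list: `lambda`, `qq` (data.frame `expected`, `observed`).
#' @export
genomicInflation <- function(res) {
  z <- res$z[!is.na(res$z)]
  if (length(z) < 10) stop("need >= 10 estimable markers")
  lambda <- stats::median(z^2) / stats::qchisq(0.5, df = 1)
  obs <- sort(res$neglog10p[!is.na(res$neglog10p)], decreasing = TRUE)
  nq <- length(obs)
  qq <- data.frame(expected = -log10(seq_len(nq) / (nq + 1)),
                   observed = obs)
  list(lambda = lambda, qq = qq)
}
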