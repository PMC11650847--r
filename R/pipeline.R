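#' @importFrom grDevices png dev.off
#' @importFrom graphics abline axis points
NULL

# deterministic per-stage stream seed
stageSeed <- function(root, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root) * 10007 + h * 97003) %% 2147483629 + 1)
}

# order-independent config fingerprint (FNV-1a over the serialized object)
configHash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (v in b) h <- (bitwXor(as.integer(h %% 2^31), v) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full monitoring workflow
#'
#' Orchestrates simulate (or load) -> qc -> ne -> gwas -> genedrop ->
#' afchange -> report from one configuration, writing every stage output
#' under `outDir` together with a machine-readable run manifest
#' (`manifest.json`). Rerunning with the same config and seed reproduces
#' all stochastic stages exactly. A stage failure aborts with the stage
#' name; the partial manifest is preserved.
#'
#' @param config a list or a YAML file path. Recognized sections (all
#'   optional): `sim` (arguments to [simConfig()]), `data` (paths
#'   `pedigree`, `genotypes`, `map`, `phenotypes` to load instead of
#'   simulating), `qc` (thresholds), `gwas` (`traits`, `fixed`, `random`,
#'   `alpha`, `scanYear`), `genedrop` (`mafGrid`, `nRep`), `baselineYear`,
#'   `plots` (write Manhattan/QQ PNGs).
#' @param outDir output directory.
#' @param seed root seed; per-stage streams are derived from it by stage
#'   name.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = list(), outDir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(configHash = configHash(config), seed = seed,
                   package = as.character(utils::packageVersion("seldrift")),
                   stages = list())
  manifestPath <- file.path(outDir, "manifest.json")
  env <- new.env()
  runStage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    failed <- inherits(res, "error")
    manifest$stages[[name]] <<- list(
      status = if (failed) "failed" else "ok",
      outputs = if (failed) character(0) else as.character(res))
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA)
    if (failed)
      stop("pipeline failed at stage '", name, "': ",
           conditionMessage(res), call. = FALSE)
  }
  baseYear <- config$baselineYear

  if (!is.null(config$data)) {
    runStage("load", function() {
      env$ped <- readPedigree(config$data$pedigree)
      env$genoRaw <- readGenotypes(config$data$genotypes,
                                   mapPath = config$data$map)
      env$phenoPath <- config$data$phenotypes
      character(0)
    })
  } else {
    runStage("simulate", function() {
      cfg <- do.call(simConfig, if (is.null(config$sim)) list() else config$sim)
      sim <- simulatePopulation(cfg, seed = stageSeed(seed, "simulate"))
      env$ped <- sim$pedigree
      env$genoRaw <- sim$genotypes
      env$sim <- sim
      paths <- writeDataset(sim, file.path(outDir, "data"))
      env$phenoPath <- paths[["phenotypes"]]
      paths
    })
  }
  if (is.null(baseYear)) {
    rec <- pedRecords(env$ped)
    baseYear <- min(floor(rec$birth[rec$genotyped]), na.rm = TRUE)
  }

  runStage("qc", function() {
    qcArgs <- if (is.null(config$qc)) list() else config$qc
    q <- do.call(qcGenotypes, c(list(env$genoRaw, env$ped), qcArgs))
    env$geno <- q$genotypes
    env$genoImp <- imputeMean(q$genotypes)
    p <- file.path(outDir, "qc_report.json")
    jsonlite::write_json(q$report, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    p
  })

  rec <- pedRecords(env$ped)
  lines <- sort(unique(rec$line[rec$genotyped & !is.na(rec$line)]))

  runStage("ne", function() {
    out <- character(0)
    for (ln in lines) {
      series <- meanKinshipByYear(env$ped, line = ln)
      L <- generationInterval(env$ped,
                              ids = rec$id[rec$genotyped & rec$line == ln])
      est <- estimateNe(series, L)
      p <- file.path(outDir, paste0("ne_line", ln, ".json"))
      writeNeReport(est, p)
      out <- c(out, p)
    }
    out
  })

  gw <- if (is.null(config$gwas)) list() else config$gwas
  traits <- if (is.null(gw$traits)) "trait1" else gw$traits
  alpha <- if (is.null(gw$alpha)) 0.05 else gw$alpha

  runStage("gwas", function() {
    if (!file.exists(env$phenoPath))
      stop("phenotype file not found: ", env$phenoPath)
    pheno <- utils::read.table(env$phenoPath, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    out <- character(0)
    env$gwas <- list()
    for (ln in lines) {
      ph <- pheno[pheno$line == ln, , drop = FALSE]
      ids <- intersect(ph$animal, animalIds(env$genoImp))
      ph <- ph[ph$animal %in% ids, , drop = FALSE]
      # drop markers monomorphic within this line before the GRM
      genoLn <- qcGenotypes(env$genoImp[, ids])$genotypes
      grm <- computeGrm(genoLn)
      for (tr in traits) {
        des <- gwasDesign(ph, trait = tr,
                          fixed = intersect(if (is.null(gw$fixed)) "sex" else gw$fixed, names(ph)),
                          random = intersect(if (is.null(gw$random)) character(0) else gw$random, names(ph)))
        vc <- remlNull(des, grm)
        res <- snpScan(des, grm, vc, genoLn)
        res$significant <- !is.na(res$neglog10p) &
          res$neglog10p >= bonferroniThreshold(alpha, sum(!is.na(res$p)))
        p <- file.path(outDir, sprintf("gwas_line%s_%s.tsv", ln, tr))
        utils::write.table(res, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        infl <- genomicInflation(res)
        env$gwas[[paste(ln, tr)]] <- res
        out <- c(out, p)
        if (isTRUE(config$plots)) {
          pp <- file.path(outDir, sprintf("manhattan_line%s_%s.png", ln, tr))
          grDevices::png(pp, width = 900, height = 300)
          plotManhattan(res, threshold = bonferroniThreshold(alpha, nrow(res)),
                        main = sprintf("line %s, %s (lambda=%.2f)", ln, tr,
                                       infl$lambda))
          grDevices::dev.off()
          out <- c(out, pp)
        }
      }
    }
    out
  })

  gd <- if (is.null(config$genedrop)) list() else config$genedrop
  runStage("genedrop", function() {
    cohorts <- stats::setNames(lapply(lines, function(ln)
      cohortList(env$ped, line = ln)), lines)
    cfg <- geneDropConfig(
      cohorts, baselineYear = baseYear,
      mafGrid = if (is.null(gd$mafGrid)) seq(0.01, 0.5, 0.01) else gd$mafGrid,
      nRep = if (is.null(gd$nRep)) 1000 else gd$nRep)
    traj <- runGeneDropping(env$ped, cfg, seed = stageSeed(seed, "genedrop"))
    env$envlp <- driftChangeDistribution(traj, baselineYear = baseYear)
    p <- file.path(outDir, "drift_envelope.tsv")
    writeEnvelope(env$envlp, p)
    p
  })

  runStage("afchange", function() {
    out <- character(0)
    env$chg <- list()
    for (ln in lines) {
      af <- alleleFreqByCohort(env$geno,
                               cohortList(env$ped, line = ln), line = ln)
      chg <- absChangeVsBaseline(af, baseYear)
      env$chg[[ln]] <- chg
      p1 <- file.path(outDir, paste0("afchange_line", ln, ".tsv"))
      utils::write.table(chg, p1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      strat <- mafStratifiedSummary(chg)
      p2 <- file.path(outDir, paste0("afchange_strata_line", ln, ".tsv"))
      utils::write.table(strat, p2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out <- c(out, p1, p2)
    }
    cmp <- lapply(lines, function(ln)
      compareToDrift(env$chg[[ln]], env$envlp)$summary)
    names(cmp) <- lines
    extra <- list(driftComparison = cmp)
    if (length(lines) >= 2) {
      yrs <- intersect(unique(env$chg[[1]]$year), unique(env$chg[[2]]$year))
      yr <- max(yrs)
      r2 <- betweenLineCorrelation(env$chg[[lines[1]]], env$chg[[lines[2]]],
                                   year = yr)
      extra$betweenLineR2 <- list(year = yr, r2 = as.numeric(r2),
                                  n = attr(r2, "n"))
    }
    p3 <- file.path(outDir, "afchange_summary.json")
    jsonlite::write_json(extra, p3, auto_unbox = TRUE, digits = NA)
    c(out, p3)
  })

  runStage("report", function() {
    p <- file.path(outDir, "report.md")
    con <- file(p, "w"); on.exit(close(con))
    cat("# Selection and drift monitoring report\n\n", file = con)
    cat(sprintf("Seed %d, config %s.\n\n", seed, manifest$configHash),
        file = con)
    for (ln in lines) {
      ne <- jsonlite::read_json(file.path(outDir, paste0("ne_line", ln, ".json")))
      cat(sprintf("- line %s: dF/year = %.4f, L = %.2f years, Ne = %s\n",
                  ln, ne$deltaFYear, ne$generationInterval,
                  if (isTRUE(ne$defined)) sprintf("%.0f", ne$neDisplay) else "undefined"),
          file = con)
    }
    for (nm in names(env$gwas)) {
      res <- env$gwas[[nm]]
      cat(sprintf("- GWAS %s: %d markers scanned, %d significant (max -log10 p = %.2f)\n",
                  nm, sum(!is.na(res$p)), sum(res$significant, na.rm = TRUE),
                  max(res$neglog10p, na.rm = TRUE)), file = con)
    }
    p
  })

  manifest$files <- list.files(outDir, recursive = TRUE)
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Minimal Manhattan plot
#'
#' @param res GwasResult data.frame.
#' @param threshold -log10 p line to draw.
#' @param main plot title.
#' @export
plotManhattan <- function(res, threshold = NULL, main = "") {
  d <- res[!is.na(res$neglog10p), ]
  chr <- factor(d$chrom)
  off <- c(0, cumsum(tapply(d$pos, chr, max)))
  x <- d$pos + off[as.integer(chr)]
  plot(x, d$neglog10p, pch = 20, cex = 0.5,
       col = c("grey30", "steelblue")[1 + as.integer(chr) %% 2],
       xlab = "genome position", ylab = "-log10 p", main = main, xaxt = "n")
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 3)
}
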