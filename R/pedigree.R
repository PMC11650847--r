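#' Read a pedigree file
#'
#' Reads a delimited pedigree file, normalizes unknown parents, auto-adds
#' parent-only ids as founder records, checks for duplicate ids, cycles and
#' parent/offspring birth-order conflicts, and returns a topologically
#' ordered [Pedigree-class].
#'
#' Unknown parents may be coded `"0"`, `""` or `"NA"`. Birth dates may be
#' ISO-8601 dates or bare years; they are stored as decimal years.
#'
#' @param path file path.
#' @param columns named character vector mapping the roles `id`, `sire`,
#'   `dam`, `birth`, `sex`, `line`, `genotyped` to column names in the file.
#'   Roles absent from the file get defaults (sex `"unknown"`, a single
#'   line `"1"`, genotyped `TRUE`).
#' @param sep field separator (default `","`).
#' @param allowDateConflicts if `TRUE`, a parent recorded as born at/after
#'   its offspring is a warning instead of an error.
#' @return a [Pedigree-class]. Ids that appeared only in a parent column are
#'   appended as founders with unknown birth time and listed in the
#'   `autoAdded` slot.
#' @seealso [asPedigree()] for in-memory data.
#' @export
readPedigree <- function(path,
                         columns = c(id = "id", sire = "sire", dam = "dam",
                                     birth = "birth_date", sex = "sex",
                                     line = "line", genotyped = "genotyped"),
                         sep = ",", allowDateConflicts = FALSE) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  get <- function(role, default) {
    cn <- columns[role]
    if (!is.na(cn) && cn %in% names(raw)) raw[[cn]] else default
  }
  n <- nrow(raw)
  id <- get("id", NULL)
  if (is.null(id)) stop("pedigree file lacks an id column")
  df <- data.frame(id = id,
                   sire = get("sire", rep(NA_character_, n)),
                   dam = get("dam", rep(NA_character_, n)),
                   birth = get("birth", rep(NA_character_, n)),
                   sex = get("sex", rep("unknown", n)),
                   line = get("line", rep("1", n)),
                   genotyped = get("genotyped", rep("1", n)),
                   stringsAsFactors = FALSE)
  asPedigree(df, allowDateConflicts = allowDateConflicts)
}

#' Build a validated Pedigree from a data.frame
#'
#' @param df data.frame with columns `id`, `sire`, `dam` and optionally
#'   `birth` (year or ISO date), `sex`, `line`, `genotyped`.
#' @inheritParams readPedigree
#' @return a [Pedigree-class] in topological order.
#' @export
asPedigree <- function(df, allowDateConflicts = FALSE) {
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    stop("duplicate animal id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  norm <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA", "na", ".")] <- NA_character_
    x
  }
  df$sire <- norm(if (is.null(df$sire)) NA else df$sire)
  df$dam <- norm(if (is.null(df$dam)) NA else df$dam)
  df$birth <- parseBirth(if (is.null(df$birth)) NA else df$birth)
  df$sex <- as.character(if (is.null(df$sex)) "unknown" else df$sex)
  df$line <- as.character(if (is.null(df$line)) "1" else df$line)
  g <- if (is.null(df$genotyped)) TRUE else df$genotyped
  df$genotyped <- if (is.logical(g)) g else as.character(g) %in% c("1", "TRUE", "true", "T", "yes")
  df <- df[, c("id", "sire", "dam", "birth", "sex", "line", "genotyped")]

  # parents never listed as animals become founders
  parentOnly <- setdiff(c(df$sire, df$dam), c(df$id, NA))
  if (length(parentOnly)) {
    sexGuess <- ifelse(parentOnly %in% df$sire, "male", "female")
    add <- data.frame(id = parentOnly, sire = NA_character_,
                      dam = NA_character_, birth = NA_real_, sex = sexGuess,
                      line = NA_character_, genotyped = FALSE,
                      stringsAsFactors = FALSE)
    df <- rbind(df, add)
  }

  ord <- topoOrder(df$id, df$sire, df$dam)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL

  # birth-order check: known parent must be born strictly before offspring
  pos <- stats::setNames(seq_len(nrow(df)), df$id)
  for (col in c("sire", "dam")) {
    p <- df[[col]]
    k <- which(!is.na(p) & !is.na(df$birth) & !is.na(df$birth[pos[p]]))
    bad <- k[df$birth[pos[p[k]]] >= df$birth[k]]
    if (length(bad)) {
      msg <- sprintf("%s of %s born at/after offspring (%s >= %s)",
                     col, df$id[bad[1]], format(df$birth[pos[p[bad[1]]]]),
                     format(df$birth[bad[1]]))
      if (allowDateConflicts) warning(msg) else stop(msg)
    }
  }
  methods::new("Pedigree", records = df,
               autoAdded = as.character(parentOnly))
}

# decimal years from bare years or ISO dates
parseBirth <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  out <- suppressWarnings(as.numeric(x))
  isDate <- is.na(out) & !is.na(x) & grepl("-", x)
  if (any(isDate)) {
    d <- as.Date(x[isDate])
    out[isDate] <- as.numeric(format(d, "%Y")) +
      (as.numeric(format(d, "%j")) - 1) / 365.25
  }
  out
}

# Kahn topological sort; on failure report one cycle
topoOrder <- function(id, sire, dam) {
  n <- length(id)
  pos <- stats::setNames(seq_len(n), id)
  par1 <- ifelse(is.na(sire), 0L, pos[sire])
  par2 <- ifelse(is.na(dam), 0L, pos[dam])
  nkids <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) for (p in c(par1[i], par2[i])) if (p > 0) {
    kids[[p]] <- c(kids[[p]], i)
  }
  indeg <- (par1 > 0) + (par2 > 0)
  # self-parenthood is a 1-cycle
  self <- which(par1 == seq_len(n) | par2 == seq_len(n))
  if (length(self))
    stop("pedigree cycle detected: ", id[self[1]], " -> ", id[self[1]])
  queue <- which(indeg == 0)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    ord <- c(ord, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    left <- setdiff(seq_len(n), ord)
    # walk parent links among leftovers until an id repeats
    path <- left[1]
    repeat {
      i <- path[length(path)]
      nxt <- c(par1[i], par2[i])
      nxt <- nxt[nxt %in% left][1]
      if (nxt %in% path) {
        cyc <- c(path[which(path == nxt):length(path)], nxt)
        stop("pedigree cycle detected: ",
             paste(id[cyc], collapse = " -> "))
      }
      path <- c(path, nxt)
    }
  }
  ord
}

#' Pedigree additive (numerator) relationships for a subset of animals
#'
#' Computes the numerator relationship matrix A by the tabular method over
#' the ancestor closure of the requested animals (provably identical to
#' using the full pedigree) and returns the block for `ids`. Diagonals are
#' 1 + F_i with F_i the inbreeding coefficient.
#'
#' @param ped a [Pedigree-class].
#' @param ids animal ids (default: all).
#' @return symmetric numeric matrix with `ids` as dimnames.
#' @export
additiveRelationship <- function(ped, ids = pedIds(ped)) {
  rec <- ped@records
  miss <- setdiff(ids, rec$id)
  if (length(miss))
    stop("id(s) not in pedigree: ", paste(utils::head(miss, 5), collapse = ", "))
  pos <- stats::setNames(seq_len(nrow(rec)), rec$id)
  # ancestor closure, as a logical over record rows
  inC <- logical(nrow(rec))
  inC[pos[ids]] <- TRUE
  for (i in rev(seq_len(nrow(rec)))) {
    if (inC[i]) {
      for (p in c(rec$sire[i], rec$dam[i]))
        if (!is.na(p)) inC[pos[p]] <- TRUE
    }
  }
  rows <- which(inC)                      # record order = topological
  newPos <- integer(nrow(rec)); newPos[rows] <- seq_along(rows)
  sire <- rec$sire[rows]; dam <- rec$dam[rows]
  si <- ifelse(is.na(sire), 0L, newPos[pos[sire]]) - 1L
  di <- ifelse(is.na(dam), 0L, newPos[pos[dam]]) - 1L
  A <- cpp_tabular_a(as.integer(si), as.integer(di))
  dimnames(A) <- list(rec$id[rows], rec$id[rows])
  A[ids, ids, drop = FALSE]
}

#' Inbreeding coefficients
#'
#' @inheritParams additiveRelationship
#' @return named numeric vector of F_i.
#' @export
inbreedingCoef <- function(ped, ids = pedIds(ped)) {
  diag(additiveRelationship(ped, ids)) - 1
}

#' Mean kinship by birth-year cohort
#'
#' For each calendar year, the mean kinship f_t among the genotyped animals
#' born that year: half the average off-diagonal element of the pedigree
#' relationship matrix over the cohort (unordered pairs; identical either
#' way by symmetry). Years with fewer than two cohort members are dropped
#' with a warning.
#'
#' @param ped a [Pedigree-class].
#' @param years calendar years to use (default: all years with genotyped
#'   animals).
#' @param line restrict to one line label (default: all lines pooled).
#' @param genotypedOnly restrict cohorts to genotyped animals (default).
#' @return data.frame `year`, `f`, `nPairs` (unordered pairs m(m-1)/2),
#'   `n` (cohort size).
#' @export
meanKinshipByYear <- function(ped, years = NULL, line = NULL,
                              genotypedOnly = TRUE) {
  rec <- ped@records
  keep <- !is.na(rec$birth)
  if (genotypedOnly) keep <- keep & rec$genotyped
  if (!is.null(line)) keep <- keep & !is.na(rec$line) & rec$line == line
  yr <- floor(rec$birth)
  if (is.null(years)) years <- sort(unique(yr[keep]))
  cohorts <- lapply(years, function(y) rec$id[keep & yr == y])
  small <- lengths(cohorts) < 2
  if (any(small)) {
    warning("dropping year(s) with < 2 cohort members: ",
            paste(years[small], collapse = ", "))
    years <- years[!small]; cohorts <- cohorts[!small]
  }
  if (!length(years)) stop("no usable cohorts")
  all <- unlist(cohorts)
  A <- additiveRelationship(ped, all)
  res <- lapply(seq_along(years), function(k) {
    idsK <- cohorts[[k]]
    B <- A[idsK, idsK]
    m <- length(idsK)
    off <- B[upper.tri(B)]
    data.frame(year = years[k], f = 0.5 * mean(off),
               nPairs = m * (m - 1) / 2, n = m)
  })
  do.call(rbind, res)
}

#' Generation interval
#'
#' Mean age of parents at the birth of their offspring, over all
#' (offspring, known parent) links with both birth times known.
#'
#' @param ped a [Pedigree-class].
#' @param ids offspring ids to use (default: genotyped animals).
#' @return L in years, with attribute `nLinks` (links used) and
#'   `nSkipped` (links dropped for a missing birth time).
#' @export
generationInterval <- function(ped, ids = NULL) {
  rec <- ped@records
  if (is.null(ids)) ids <- rec$id[rec$genotyped]
  rows <- match(ids, rec$id)
  if (anyNA(rows)) stop("id(s) not in pedigree")
  pos <- stats::setNames(seq_len(nrow(rec)), rec$id)
  gaps <- numeric(0); skipped <- 0L
  for (col in c("sire", "dam")) {
    p <- rec[[col]][rows]
    known <- !is.na(p)
    pb <- rep(NA_real_, length(p)); pb[known] <- rec$birth[pos[p[known]]]
    ok <- known & !is.na(pb) & !is.na(rec$birth[rows])
    skipped <- skipped + sum(known & !ok)
    gaps <- c(gaps, rec$birth[rows][ok] - pb[ok])
  }
  if (!length(gaps)) stop("no usable parent-offspring links with birth times")
  structure(mean(gaps), nLinks = length(gaps), nSkipped = skipped)
}

#' Effective population size from a kinship-by-year series
#'
#' Regresses ln(1 - f_t) on calendar year by ordinary least squares; the
#' rate of inbreeding per year is dF_year = 1 - exp(b), per generation
#' dF_gen = L * dF_year, and Ne = 1 / (2 dF_gen). When kinship is
#' non-increasing (dF_gen <= 0) Ne is reported as undefined with a flag
#' rather than an error.
#'
#' @param series data.frame with columns `year` and `f` (e.g. from
#'   [meanKinshipByYear()]).
#' @param L generation interval in years (e.g. from [generationInterval()]).
#' @return a [NeEstimate-class]. The display value is rounded half-to-even.
#' @export
estimateNe <- function(series, L) {
  stopifnot(is.data.frame(series), all(c("year", "f") %in% names(series)),
            length(L) == 1, L > 0)
  if (nrow(series) < 3) stop("need at least 3 yearly cohorts")
  if (any(series$f >= 1)) stop("f_t must be < 1")
  fit <- stats::lm(log(1 - f) ~ year, data = series)
  b <- unname(stats::coef(fit)["year"])
  dfYear <- 1 - exp(b)
  dfGen <- L * dfYear
  defined <- dfGen > 0
  ne <- if (defined) 1 / (2 * dfGen) else NA_real_
  methods::new("NeEstimate", slope = b, deltaFYear = dfYear,
               generationInterval = as.numeric(L), deltaFGen = dfGen,
               ne = ne, neDisplay = if (defined) round(ne) else NA_real_,
               defined = defined, nYears = nrow(series),
               series = series)
}

#' Write an Ne report (JSON)
#'
#' @param est a [NeEstimate-class].
#' @param path output path; `.json` written via jsonlite.
#' @return `path`, invisibly.
#' @export
writeNeReport <- function(est, path) {
  out <- list(slope = est@slope, deltaFYear = est@deltaFYear,
              generationInterval = est@generationInterval,
              deltaFGen = est@deltaFGen, ne = est@ne,
              neDisplay = est@neDisplay, defined = est@defined,
              nYears = est@nYears,
              series = est@series)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
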