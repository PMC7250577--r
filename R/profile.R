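# position-specific profiles, E-value calibration, database search and the
# sliding-window provenance scan

#' Build a position-specific scoring profile from an alignment
#'
#' Per-column residue frequencies are estimated with a
#' background-proportional pseudocount:
#' `freq = (counts + w * background) / (n_residues + w)`, and match scores
#' are `log2(freq / background)` (bits). Columns whose occupancy falls below
#' `minColumnOccupancy` are excluded from the model so gap-dominated columns
#' cannot carry signal; `columnMap` records the retained source columns.
#'
#' @param alignment a [SeqAlignment-class].
#' @param pseudocountWeight weight of the background pseudocount (> 0).
#' @param backgroundFreqs length-20 background distribution (default: LG
#'   model frequencies).
#' @param gapOpen,gapExtend affine gap penalties in bits used when scoring
#'   sequences against the profile.
#' @param minColumnOccupancy columns below this non-gap fraction are
#'   dropped from the model.
#' @param scoreFloor lower cap for match scores (keeps them finite when a
#'   residue is unobserved and the pseudocount is tiny).
#' @return an uncalibrated [ProfileModel-class].
#' @export
buildProfile <- function(alignment, pseudocountWeight = 1.0,
                         backgroundFreqs = NULL, gapOpen = 4,
                         gapExtend = 0.5, minColumnOccupancy = 0.5,
                         scoreFloor = -20) {
  if (length(alignment@rows) == 0) stop("alignment must be non-empty")
  if (pseudocountWeight <= 0) stop("pseudocountWeight must be positive")
  if (is.null(backgroundFreqs))
    backgroundFreqs <- unname(lgModel()@equilibriumFreqs)
  m <- gapMatrix(alignment@rows)
  occ <- colMeans(m != "-")
  keep <- which(occ >= minColumnOccupancy)
  if (!length(keep)) stop("no alignment column reaches the minimum occupancy")
  scores <- matrix(0, 20, length(keep))
  for (kk in seq_along(keep)) {
    cc <- aaCodes(paste(m[, keep[kk]], collapse = ""))
    cc <- cc[!is.na(cc)]
    cnt <- tabulate(cc, 20)
    freq <- (cnt + pseudocountWeight * backgroundFreqs) /
      (length(cc) + pseudocountWeight)
    scores[, kk] <- pmax(log2(freq / backgroundFreqs), scoreFloor)
  }
  rownames(scores) <- AA_ALPHABET20
  new("ProfileModel", matchScores = scores,
      backgroundFreqs = backgroundFreqs, gapOpen = gapOpen,
      gapExtend = gapExtend, pseudocountWeight = pseudocountWeight,
      columnMap = as.integer(keep), calibration = list())
}

#' Sliding-window profiles over an alignment
#'
#' Windows start at columns 1, 1+step, ...; their count is
#' `floor((n_columns - windowSize) / step) + 1`. Each window is turned into
#' its own profile with [buildProfile()].
#'
#' @param alignment a [SeqAlignment-class] with at least `windowSize`
#'   columns.
#' @param windowSize window width in alignment columns (default 60).
#' @param step window step in columns (default 1).
#' @param ... passed to [buildProfile()].
#' @return list of `list(start, profile)` entries.
#' @export
windowProfiles <- function(alignment, windowSize = 60L, step = 1L, ...) {
  L <- nColumns(alignment)
  if (windowSize > L) stop("windowSize exceeds the number of columns")
  if (step < 1L) stop("step must be >= 1")
  starts <- seq(1L, L - windowSize + 1L, by = step)
  m <- gapMatrix(alignment@rows)
  ids <- names(alignment@rows)
  lapply(starts, function(s) {
    sub <- new("SeqAlignment",
               rows = matrixToRows(m[, s:(s + windowSize - 1L), drop = FALSE],
                                   ids))
    list(start = as.integer(s), profile = buildProfile(sub, ...))
  })
}

# score matrix of a profile against residue codes (X and unknown score 0)
profileScoreMatrix <- function(profile, codes) {
  n <- ncol(profile@matchScores)
  S <- matrix(0, n, length(codes))
  ok <- !is.na(codes)
  if (any(ok)) S[, ok] <- t(profile@matchScores)[, codes[ok], drop = FALSE]
  S
}

#' Best local match of a profile in a sequence
#'
#' Smith-Waterman-style local alignment of the profile against the sequence
#' under the profile's match scores and affine gap penalties. The score is
#' never negative; a sequence with no positive-scoring segment returns
#' score 0 and an empty envelope. Ties resolve to the earliest segment.
#'
#' @param profile a [ProfileModel-class].
#' @param seq non-empty residue string.
#' @return list with `score` (bits), `targetStart`/`targetEnd` (1-based
#'   envelope in the sequence; 0/0 when empty) and
#'   `profileStart`/`profileEnd`.
#' @export
scoreProfileLocal <- function(profile, seq) {
  if (!nzchar(seq)) stop("sequence must be non-empty")
  codes <- aaCodes(seq)
  res <- cpp_affine_local(profileScoreMatrix(profile, codes),
                          profile@gapOpen, profile@gapExtend)
  list(score = res$score, targetStart = res$col_start,
       targetEnd = res$col_end, profileStart = res$row_start,
       profileEnd = res$row_end)
}

# residue-shuffled decoy drawn from the database's own sequences
shuffleDecoy <- function(seqs) {
  s <- seqs[[sample.int(length(seqs), 1L)]]
  paste(sample(strsplit(s, "")[[1]]), collapse = "")
}

#' Calibrate profile E-values on shuffled decoys
#'
#' Scores the profile against length-matched residue-shuffled decoys drawn
#' from the database and fits a Gumbel law to the per-sequence maximal
#' scores (method of moments). The E-value of a score s is then
#' `dbSize * P(Score >= s)`: the expected number of database records
#' scoring at least s under the null, so E is strictly decreasing in s and
#' scales linearly with database size.
#'
#' @param profile a [ProfileModel-class].
#' @param db a [TaxSeqDB-class] providing decoy material and the database
#'   size.
#' @param nDecoys number of decoys (>= 100).
#' @param seed integer seed for decoy generation.
#' @return the profile with its `calibration` slot filled.
#' @export
calibrateEvalue <- function(profile, db, nDecoys = 200L, seed = 1L) {
  if (nDecoys < 100L) stop("nDecoys must be >= 100")
  seqs <- dbSequences(db)
  seqs <- seqs[order(names(seqs))] # invariance to record order
  set.seed(seed)
  scores <- vapply(seq_len(nDecoys), function(i)
    scoreProfileLocal(profile, shuffleDecoy(seqs))$score, numeric(1))
  if (stats::sd(scores) < 1e-9)
    stop("E-value calibration failed: decoy scores are constant")
  # maximum-likelihood Gumbel fit (fixed-point iteration on the scale);
  # the moments estimator misfits the tail, which is what E-values live on
  beta <- stats::sd(scores) * sqrt(6) / pi
  for (it in 1:50) {
    w <- exp(-scores / beta)
    betaNew <- mean(scores) - sum(scores * w) / sum(w)
    if (!is.finite(betaNew) || betaNew <= 0) break
    if (abs(betaNew - beta) < 1e-10) { beta <- betaNew; break }
    beta <- betaNew
  }
  mu <- -beta * log(mean(exp(-scores / beta)))
  profile@calibration <- list(location = mu, scale = beta,
                              dbSize = length(db),
                              nDecoys = as.integer(nDecoys),
                              seed = as.integer(seed))
  profile
}

#' E-value of a score under a profile's calibration
#' @param profile a calibrated [ProfileModel-class].
#' @param score bit score(s).
#' @param dbSize optional database size override.
#' @return E-value(s), strictly decreasing in score.
#' @export
evalueForScore <- function(profile, score, dbSize = NULL) {
  cal <- profile@calibration
  if (!length(cal)) stop("profile is not calibrated; run calibrateEvalue()")
  if (is.null(dbSize)) dbSize <- cal$dbSize
  z <- (score - cal$location) / cal$scale
  p <- -expm1(-exp(-z)) # 1 - exp(-exp(-z)), numerically safe
  pmax(dbSize * p, .Machine$double.xmin)
}

#' Search a database with a calibrated profile
#'
#' @param profile a calibrated [ProfileModel-class].
#' @param db a [TaxSeqDB-class].
#' @param eThreshold report hits with E-value at or below this (the two
#'   conventional thresholds are 10 for permissive single-domain searches
#'   and 0.01 for stringent ones).
#' @return data.frame of hits sorted by ascending E-value (ties by id):
#'   target_id, score, e_value, target_start, target_end, profile_start,
#'   profile_end.
#' @export
searchDatabase <- function(profile, db, eThreshold = 0.01) {
  if (!length(profile@calibration))
    stop("profile is not calibrated; run calibrateEvalue()")
  seqs <- dbSequences(db)
  if (!length(seqs))
    return(data.frame(target_id = character(0), score = numeric(0),
                      e_value = numeric(0), target_start = integer(0),
                      target_end = integer(0), profile_start = integer(0),
                      profile_end = integer(0)))
  res <- lapply(seqs, function(s) scoreProfileLocal(profile, s))
  hits <- data.frame(
    target_id = names(seqs),
    score = vapply(res, `[[`, numeric(1), "score"),
    e_value = evalueForScore(profile,
                             vapply(res, `[[`, numeric(1), "score")),
    target_start = vapply(res, `[[`, numeric(1), "targetStart"),
    target_end = vapply(res, `[[`, numeric(1), "targetEnd"),
    profile_start = vapply(res, `[[`, numeric(1), "profileStart"),
    profile_end = vapply(res, `[[`, numeric(1), "profileEnd"),
    row.names = NULL, stringsAsFactors = FALSE)
  hits <- hits[hits$e_value <= eThreshold, , drop = FALSE]
  hits[order(hits$e_value, hits$target_id), , drop = FALSE]
}

#' Calibrate a list of window profiles against one decoy set
#'
#' @param windows output of [windowProfiles()].
#' @param db a [TaxSeqDB-class].
#' @param nDecoys decoys per window (>= 100).
#' @param seed integer seed; each window derives its own sub-seed.
#' @return the windows with calibrated profiles.
#' @export
calibrateWindows <- function(windows, db, nDecoys = 120L, seed = 1L) {
  lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    w$profile <- calibrateEvalue(w$profile, db, nDecoys,
                                 splitSeed(seed, i))
    w
  })
}

#' Reduce a database to the union of profile hits
#'
#' Consolidates the hits of one or more profiles (at a permissive E-value)
#' into a smaller database. Running the windowed provenance scan against
#' such a reduced database suppresses spurious matches that short windows
#' would otherwise pick up in a large background.
#'
#' @param db a [TaxSeqDB-class].
#' @param profiles list of calibrated [ProfileModel-class] objects.
#' @param eThreshold permissive threshold for inclusion (default 10).
#' @return the reduced [TaxSeqDB-class].
#' @export
reducedDatabase <- function(db, profiles, eThreshold = 10) {
  keep <- character(0)
  for (p in profiles)
    keep <- union(keep, searchDatabase(p, db, eThreshold)$target_id)
  if (!length(keep)) stop("no profile hit at the given threshold")
  db[sort(keep)]
}

PROVENANCE_CATEGORIES <- c("Bacteria", "Archaea", "Virus",
                           "Eukaryota_focal", "Eukaryota_other", "Unknown")

#' Per-window taxonomic provenance of database hits
#'
#' For every sliding window, searches the database with that window's
#' profile and counts the hits by taxonomic category: Bacteria, Archaea,
#' Virus, eukaryotes split into the focal category and all others, plus
#' Unknown. This is the table behind a stacked provenance plot of a
#' two-domain protein: windows inside a horizontally acquired domain show a
#' majority of hits from the donor domain of life.
#'
#' @param windows calibrated windows from [calibrateWindows()].
#' @param db a [TaxSeqDB-class].
#' @param eThreshold E-value threshold per window search.
#' @param focalCategory taxonomy category treated as the focal gene family.
#' @return a [ProvenanceProfile-class].
#' @export
provenanceProfile <- function(windows, db, eThreshold = 0.01,
                              focalCategory = "focal") {
  if (!length(windows)) stop("no windows supplied")
  tx <- db@taxonomy
  known <- tx$domain_of_life %in% setdiff(DOMAINS_OF_LIFE, "Unknown")
  if (!all(known))
    warning("records with unknown taxonomy are counted as Unknown")
  counts <- matrix(0L, length(windows), length(PROVENANCE_CATEGORIES),
                   dimnames = list(NULL, PROVENANCE_CATEGORIES))
  starts <- integer(length(windows))
  wsize <- ncol(windows[[1]]$profile@matchScores)
  for (i in seq_along(windows)) {
    starts[i] <- windows[[i]]$start
    hits <- searchDatabase(windows[[i]]$profile, db, eThreshold)
    if (!nrow(hits)) next
    m <- match(hits$target_id, tx$id)
    dom <- tx$domain_of_life[m]
    cat_ <- tx$category[m]
    lab <- ifelse(dom == "Eukaryota",
                  ifelse(cat_ == focalCategory, "Eukaryota_focal",
                         "Eukaryota_other"),
                  ifelse(dom %in% c("Bacteria", "Archaea", "Virus"), dom,
                         "Unknown"))
    tabl <- table(factor(lab, levels = PROVENANCE_CATEGORIES))
    counts[i, ] <- as.integer(tabl)
  }
  new("ProvenanceProfile", windowStarts = starts,
      windowSize = as.integer(attr(windows, "windowSize") %||% wsize),
      counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a provenance profile as a stack-plot TSV
#' @param pp a [ProvenanceProfile-class].
#' @param path output path.
#' @export
writeProvenanceTsv <- function(pp, path) {
  df <- data.frame(window_start = pp@windowStarts, pp@counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / read a profile as a self-describing TSV
#' @param profile a [ProfileModel-class].
#' @param path file path.
#' @export
writeProfileTsv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(gapOpen = profile@gapOpen, gapExtend = profile@gapExtend,
            pseudocountWeight = profile@pseudocountWeight)
  for (nm in names(meta))
    writeLines(sprintf("# %s\t%.10g", nm, meta[[nm]]), con)
  if (length(profile@calibration))
    writeLines(sprintf("# calibration\t%.10g\t%.10g\t%d",
                       profile@calibration$location,
                       profile@calibration$scale,
                       profile@calibration$dbSize), con)
  writeLines(paste0("# background\t",
                    paste(sprintf("%.10g", profile@backgroundFreqs),
                          collapse = "\t")), con)
  df <- data.frame(column = profile@columnMap,
                   t(profile@matchScores), check.names = FALSE)
  colnames(df) <- c("column", AA_ALPHABET20)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeProfileTsv
#' @export
readProfileTsv <- function(path) {
  lines <- readLines(path)
  metaLines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ml in metaLines) {
    parts <- strsplit(sub("^# ", "", ml), "\t")[[1]]
    meta[[parts[1]]] <- parts[-1]
  }
  body <- utils::read.delim(text = lines[!startsWith(lines, "# ")],
                            check.names = FALSE)
  scores <- t(as.matrix(body[, AA_ALPHABET20]))
  rownames(scores) <- AA_ALPHABET20
  cal <- if (!is.null(meta$calibration))
    list(location = as.numeric(meta$calibration[1]),
         scale = as.numeric(meta$calibration[2]),
         dbSize = as.integer(meta$calibration[3])) else list()
  new("ProfileModel", matchScores = scores,
      backgroundFreqs = as.numeric(meta$background),
      gapOpen = as.numeric(meta$gapOpen[1]),
      gapExtend = as.numeric(meta$gapExtend[1]),
      pseudocountWeight = as.numeric(meta$pseudocountWeight[1]),
      columnMap = as.integer(body$column), calibration = cal)
}
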