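# iterative discovery of two-domain (chimeric) orthologs

#' Find sequences carrying both domains in the required architecture
#'
#' A database record is a positive architecture hit when both profiles match
#' it at or below the E-value threshold and the domain-A envelope lies
#' strictly N-terminal to the domain-B envelope. No length, composition or
#' conservation requirement is placed on the inter-domain (linker) segment;
#' abutting domains give an empty linker. Records where both domains match
#' but the envelopes overlap (or, with `enforceOrder`, appear in the wrong
#' order) are rejected with a logged reason, not an error.
#'
#' @param db a [TaxSeqDB-class].
#' @param profileA,profileB calibrated [ProfileModel-class] objects for the
#'   N-terminal and C-terminal domains.
#' @param eThreshold per-domain E-value threshold (default 0.01).
#' @param enforceOrder require A strictly before B (the canonical
#'   architecture); set FALSE to accept either order.
#' @return data.frame with one row per accepted hit: target_id,
#'   a_start/a_end, b_start/b_end, linker_start/linker_end (NA when the
#'   linker is empty), a_evalue, b_evalue. Rejected two-domain records are
#'   attached as the `rejected` attribute with a `reason` column.
#' @export
findArchitectureHits <- function(db, profileA, profileB, eThreshold = 0.01,
                                 enforceOrder = TRUE) {
  hitsA <- searchDatabase(profileA, db, eThreshold)
  hitsB <- searchDatabase(profileB, db, eThreshold)
  common <- intersect(hitsA$target_id, hitsB$target_id)
  out <- list()
  rejected <- list()
  for (id in sort(common)) {
    ha <- hitsA[hitsA$target_id == id, ][1, ]
    hb <- hitsB[hitsB$target_id == id, ][1, ]
    if (!enforceOrder && hb$target_end < ha$target_start) {
      # relaxed mode: report the N-terminal match in the a_* columns
      tmp <- ha; ha <- hb; hb <- tmp
    }
    if (ha$target_end < hb$target_start) {
      linkerLen <- hb$target_start - ha$target_end - 1L
      out[[id]] <- data.frame(
        target_id = id,
        a_start = ha$target_start, a_end = ha$target_end,
        b_start = hb$target_start, b_end = hb$target_end,
        linker_start = if (linkerLen > 0) ha$target_end + 1L else NA_integer_,
        linker_end = if (linkerLen > 0) hb$target_start - 1L else NA_integer_,
        a_evalue = ha$e_value, b_evalue = hb$e_value,
        stringsAsFactors = FALSE)
    } else {
      rejected[[id]] <- data.frame(
        target_id = id,
        reason = if (ha$target_start > hb$target_end)
          "domains in reverse order" else "domain envelopes overlap",
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(target_id = character(0), a_start = integer(0),
               a_end = integer(0), b_start = integer(0), b_end = integer(0),
               linker_start = integer(0), linker_end = integer(0),
               a_evalue = numeric(0), b_evalue = numeric(0))
  rownames(res) <- NULL
  attr(res, "rejected") <- if (length(rejected)) do.call(rbind, rejected)
    else data.frame(target_id = character(0), reason = character(0))
  res
}

#' Iterative two-domain ortholog discovery to convergence
#'
#' Starting from seed alignments of the two domains, each round builds and
#' calibrates per-domain profiles, collects architecture hits, aligns the
#' newly found domain segments back to the profiles and appends them to the
#' alignments, then repeats. Iteration stops when a round adds no new ids
#' (a fixed point, so the confirming round is counted) or when `maxRounds`
#' is reached, in which case the state is flagged non-converged. The
#' accepted id set grows monotonically by construction.
#'
#' @param db a [TaxSeqDB-class].
#' @param seedA,seedB seed [SeqAlignment-class] objects for the two domains.
#' @param eThreshold per-domain E-value threshold.
#' @param maxRounds maximum number of search rounds.
#' @param nDecoys decoys per calibration.
#' @param seed integer seed (per-round calibration seeds derive from it).
#' @param enforceOrder as in [findArchitectureHits()].
#' @param ... passed to [buildProfile()].
#' @return a [DiscoveryState-class].
#' @export
iterateDiscovery <- function(db, seedA, seedB, eThreshold = 0.01,
                             maxRounds = 10L, nDecoys = 200L, seed = 1L,
                             enforceOrder = TRUE, ...) {
  if (!length(seedA@rows) || !length(seedB@rows))
    stop("seed alignments must be non-empty")
  alnA <- seedA
  alnB <- seedB
  accepted <- character(0)
  seqs <- dbSequences(db)
  logRows <- list()
  round <- 0L
  converged <- FALSE
  profA <- profB <- NULL
  hits <- NULL
  repeat {
    round <- round + 1L
    profA <- calibrateEvalue(buildProfile(alnA, ...), db, nDecoys,
                             splitSeed(seed, 2L * round))
    profB <- calibrateEvalue(buildProfile(alnB, ...), db, nDecoys,
                             splitSeed(seed, 2L * round + 1L))
    hits <- findArchitectureHits(db, profA, profB, eThreshold, enforceOrder)
    newIds <- setdiff(hits$target_id, accepted)
    logRows[[round]] <- data.frame(round = round,
                                   n_accepted = length(accepted) + length(newIds),
                                   n_new = length(newIds))
    if (!length(newIds)) {
      converged <- TRUE
      break
    }
    accepted <- c(accepted, sort(newIds))
    # a profile row covers only the modeled columns; pad the excluded ones
    expandRow <- function(profile, width, row) {
      full <- rep("-", width)
      full[profile@columnMap] <- strsplit(row, "")[[1]]
      paste(full, collapse = "")
    }
    for (id in sort(newIds)) {
      h <- hits[hits$target_id == id, ]
      segA <- substr(seqs[[id]], h$a_start, h$a_end)
      segB <- substr(seqs[[id]], h$b_start, h$b_end)
      rowA <- expandRow(profA, nColumns(alnA),
                        alignToProfile(profA, segA)$row)
      rowB <- expandRow(profB, nColumns(alnB),
                        alignToProfile(profB, segB)$row)
      alnA@rows <- c(alnA@rows, stats::setNames(rowA, id))
      alnB@rows <- c(alnB@rows, stats::setNames(rowB, id))
    }
    if (round >= maxRounds) break
  }
  new("DiscoveryState", round = round, acceptedIds = accepted,
      alignmentA = alnA, alignmentB = alnB, profileA = profA,
      profileB = profB, converged = converged,
      log = do.call(rbind, logRows))
}

#' Keep the best hit per species
#'
#' When several hits come from the same species, only the one with the
#' lowest E-value is kept (for architecture hits, the product of the two
#' domain E-values). Ties break by id.
#'
#' @param hits data.frame with a `target_id` column and either `e_value` or
#'   `a_evalue`/`b_evalue` columns.
#' @param speciesOf named character vector mapping ids to species.
#' @return the filtered data.frame, one row per species.
#' @export
dedupeBestPerSpecies <- function(hits, speciesOf) {
  if (!nrow(hits)) return(hits)
  if (anyNA(match(hits$target_id, names(speciesOf))))
    stop("speciesOf must cover every hit id")
  ev <- if ("e_value" %in% names(hits)) hits$e_value
    else hits$a_evalue * hits$b_evalue
  sp <- unname(speciesOf[hits$target_id])
  ord <- order(sp, ev, hits$target_id)
  h <- hits[ord, , drop = FALSE]
  keep <- !duplicated(sp[ord])
  out <- h[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
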