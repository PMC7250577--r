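#' Build a non-redundant sequence database
#'
#' Records with identical residue content are merged into one record. The
#' merged record keeps the lexicographically first id, unions the source
#' ids, and keeps taxonomy labels when they agree; conflicting labels become
#' `Unknown` with a warning. The operation is idempotent.
#'
#' @param db a [TaxSeqDB-class] (or anything [taxSeqDB()] accepts via
#'   `sequences`/`domain`/`category`).
#' @return a [TaxSeqDB-class] with unique residue strings.
#' @export
buildNrDatabase <- function(db) {
  seqs <- dbSequences(db)
  tx <- db@taxonomy
  groups <- split(seq_along(seqs), unname(seqs))
  ord <- order(vapply(groups, function(g) min(names(seqs)[g]), character(1)))
  groups <- groups[ord]
  outSeq <- character(0)
  outDom <- character(0)
  outCat <- character(0)
  outSrc <- list()
  conflicts <- 0L
  for (g in groups) {
    ids <- sort(names(seqs)[g])
    keep <- ids[1]
    doms <- unique(tx$domain_of_life[match(ids, tx$id)])
    cats <- unique(tx$category[match(ids, tx$id)])
    if (length(doms) > 1L) { doms <- "Unknown"; conflicts <- conflicts + 1L }
    if (length(cats) > 1L) { cats <- "Unknown"; conflicts <- conflicts + 1L }
    outSeq[keep] <- seqs[[g[1]]]
    outDom[keep] <- doms
    outCat[keep] <- cats
    outSrc[[keep]] <- sort(unique(unlist(db@sourceIds[ids])))
  }
  if (conflicts > 0L)
    warning(conflicts, " merged group(s) had conflicting taxonomy labels; ",
            "set to Unknown")
  taxSeqDB(outSeq, outDom, outCat, sourceIds = outSrc)
}
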