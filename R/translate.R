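#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1..+3 read the forward strand starting at offsets 0..2, frames
#' -1..-3 read the reverse complement the same way. Stops are `*`, codons
#' containing an ambiguity become `X`, and trailing partial codons are
#' dropped.
#'
#' @param nt nucleotide string over A, C, G, T, N (case-insensitive).
#' @return named character vector of 6 amino-acid strings
#'   (`F+1`..`F+3`, `F-1`..`F-3`).
#' @export
sixFrameTranslate <- function(nt) {
  nt <- toupper(nt)
  if (nchar(nt) < 3) stop("nucleotide sequence must have length >= 3")
  if (!grepl("^[ACGTN]+$", nt)) stop("nucleotide sequence may contain only A, C, G, T, N")
  fwd <- Biostrings::DNAString(nt)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, off) {
    len <- length(s) - off
    len <- len - len %% 3
    if (len < 3) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(s, start = off + 1L, width = len),
      if.fuzzy.codon = "X"))
  }
  out <- c(one(fwd, 0L), one(fwd, 1L), one(fwd, 2L),
           one(rev, 0L), one(rev, 1L), one(rev, 2L))
  names(out) <- c("F+1", "F+2", "F+3", "F-1", "F-2", "F-3")
  out
}

#' Longest methionine-initiated open reading frame across six frames
#'
#' Scans the translated frames for the longest stop-free segment that starts
#' with M. Ties break by frame order (+1, +2, +3, -1, -2, -3) and then by
#' the leftmost start within the frame.
#'
#' @param aaFrames output of [sixFrameTranslate()].
#' @return list with `orf` (amino-acid string, possibly empty), `frame`
#'   (frame name or NA) and `found` (FALSE when no frame has an
#'   M-initiated segment).
#' @export
longestOrf <- function(aaFrames) {
  best <- ""
  bestFrame <- NA_character_
  for (f in names(aaFrames)) {
    segs <- strsplit(aaFrames[[f]], "*", fixed = TRUE)[[1]]
    for (seg in segs) {
      m <- regexpr("M", seg, fixed = TRUE)
      if (m < 0) next
      orf <- substring(seg, m)
      if (nchar(orf) > nchar(best)) {
        best <- orf
        bestFrame <- f
      }
    }
  }
  list(orf = best, frame = bestFrame, found = nchar(best) > 0)
}

#' Translate nucleotide records into a protein database by longest ORF
#'
#' Utility for searching transcript sets: each nucleotide record is
#' six-frame translated and represented by its longest M-initiated ORF.
#' Records without an ORF are dropped.
#'
#' @param sequences named character vector of nucleotide sequences.
#' @param domain,category taxonomy labels (recycled).
#' @return a [TaxSeqDB-class] of ORF proteins; the frame of each ORF is
#'   recorded in the `orfFrames` attribute.
#' @export
translateTranscripts <- function(sequences, domain = "Unknown",
                                 category = "background") {
  orfs <- lapply(sequences, function(s) longestOrf(sixFrameTranslate(s)))
  keep <- vapply(orfs, `[[`, logical(1), "found")
  if (!any(keep)) stop("no open reading frame found in any record")
  prot <- vapply(orfs[keep], `[[`, character(1), "orf")
  db <- taxSeqDB(prot, rep_len(domain, length(sequences))[keep],
                 rep_len(category, length(sequences))[keep])
  attr(db, "orfFrames") <- vapply(orfs[keep], `[[`, character(1), "frame")
  db
}
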