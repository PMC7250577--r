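# pairwise and progressive alignment built on the shared affine-gap DP kernel

# BLOSUM62 restricted to the 20 canonical residues, in AA_ALPHABET20 order
defaultSubMatrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA_ALPHABET20, AA_ALPHABET20]
  storage.mode(m) <- "double"
  m
}

# score matrix for two residue strings; X (code NA) scores 0 everywhere
pairScoreMatrix <- function(a, b, sub) {
  ca <- aaCodes(a); cb <- aaCodes(b)
  padded <- rbind(cbind(sub, 0), 0) # 21st row/col for X
  ca[is.na(ca)] <- 21L; cb[is.na(cb)] <- 21L
  padded[ca, cb, drop = FALSE]
}

applyOps <- function(a, b, ops) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ia <- 0L; ib <- 0L
  outA <- character(length(ops)); outB <- character(length(ops))
  for (k in seq_along(ops)) {
    if (ops[k] == 0L) {
      ia <- ia + 1L; ib <- ib + 1L
      outA[k] <- ca[ia]; outB[k] <- cb[ib]
    } else if (ops[k] == 1L) {
      ia <- ia + 1L
      outA[k] <- ca[ia]; outB[k] <- "-"
    } else {
      ib <- ib + 1L
      outA[k] <- "-"; outB[k] <- cb[ib]
    }
  }
  c(paste(outA, collapse = ""), paste(outB, collapse = ""))
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch with affine gaps (a gap of length L costs
#' `gapOpen + gapExtend * L`). Ties in the traceback are broken
#' deterministically: residue pair first, then a residue of `a` over a gap,
#' then a residue of `b` over a gap, so results are bit-stable.
#'
#' @param a,b non-empty residue strings (X allowed, scored 0).
#' @param substitutionMatrix 20x20 score matrix in [AA_ALPHABET20] order
#'   (default BLOSUM62).
#' @param gapOpen,gapExtend affine gap penalties (positive).
#' @return list with `alignedA`, `alignedB` (gapped strings) and `score`.
#' @export
globalAlign <- function(a, b, substitutionMatrix = defaultSubMatrix(),
                        gapOpen = 11, gapExtend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  checkResidues(c(a, b), "sequence")
  S <- pairScoreMatrix(a, b, substitutionMatrix)
  res <- cpp_affine_global(S, gapOpen, gapExtend)
  al <- applyOps(a, b, res$ops)
  list(alignedA = al[1], alignedB = al[2], score = res$score)
}

#' Percent identity of an aligned pair
#'
#' Identity is counted over columns where both rows have a residue;
#' columns with a gap in either row are excluded. Returns 0 when no such
#' column exists.
#'
#' @param alignedA,alignedB equal-length gapped strings.
#' @return fraction in `[0, 1]`.
#' @export
percentIdentity <- function(alignedA, alignedB) {
  if (nchar(alignedA) != nchar(alignedB))
    stop("aligned strings must have equal length")
  ca <- strsplit(alignedA, "")[[1]]; cb <- strsplit(alignedB, "")[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both)) return(0)
  sum(ca[both] == cb[both]) / sum(both)
}

# fractional shared k-mer distance used for the guide tree
kmerDistance <- function(seqs, k = 3L) {
  km <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, seq_len(nchar(s) - k + 1L),
                     seq_len(nchar(s) - k + 1L) + k - 1L))
  })
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- max(1L, min(length(km[[i]]), length(km[[j]])))
      d[i, j] <- d[j, i] <- 1 - length(intersect(km[[i]], km[[j]])) / denom
    }
  }
  d
}

# per-column residue frequency profile of a character matrix (gaps weighted
# out by dividing by the row count)
columnFreqs <- function(m) {
  L <- ncol(m)
  f <- matrix(0, 20, L)
  for (j in seq_len(L)) {
    cc <- aaCodes(paste(m[, j], collapse = ""))
    cc <- cc[!is.na(cc)]
    if (length(cc)) f[, j] <- tabulate(cc, 20) / nrow(m)
  }
  f
}

mergeAlignments <- function(ma, mb, sub, gapOpen, gapExtend) {
  S <- t(columnFreqs(ma)) %*% sub %*% columnFreqs(mb)
  res <- cpp_affine_global(S, gapOpen, gapExtend)
  ops <- res$ops
  out <- matrix("", nrow(ma) + nrow(mb), length(ops))
  ia <- 0L; ib <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] == 0L) {
      ia <- ia + 1L; ib <- ib + 1L
      out[, k] <- c(ma[, ia], mb[, ib])
    } else if (ops[k] == 1L) {
      ia <- ia + 1L
      out[, k] <- c(ma[, ia], rep("-", nrow(mb)))
    } else {
      ib <- ib + 1L
      out[, k] <- c(rep("-", nrow(ma)), mb[, ib])
    }
  }
  rownames(out) <- c(rownames(ma), rownames(mb))
  out
}

#' Progressive multiple sequence alignment
#'
#' A classical progressive aligner: fractional k-mer distances, UPGMA guide
#' tree, and profile-profile merges along the tree using the affine-gap DP
#' kernel. Removing the gaps of any output row reproduces the corresponding
#' input sequence exactly.
#'
#' @param seqs named character vector of >= 2 protein sequences.
#' @param substitutionMatrix,gapOpen,gapExtend as in [globalAlign()].
#' @return a [SeqAlignment-class].
#' @export
progressiveMsa <- function(seqs, substitutionMatrix = defaultSubMatrix(),
                           gapOpen = 11, gapExtend = 1) {
  if (length(seqs) < 2L) stop("progressiveMsa needs at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  checkResidues(unname(seqs), "sequence")
  d <- kmerDistance(seqs)
  dimnames(d) <- list(names(seqs), names(seqs))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  profs <- lapply(names(seqs), function(id) {
    m <- matrix(strsplit(seqs[[id]], "")[[1]], nrow = 1)
    rownames(m) <- id
    m
  })
  merged <- vector("list", nrow(hc$merge))
  getProf <- function(x) if (x < 0) profs[[-x]] else merged[[x]]
  for (i in seq_len(nrow(hc$merge))) {
    merged[[i]] <- mergeAlignments(getProf(hc$merge[i, 1]),
                                   getProf(hc$merge[i, 2]),
                                   substitutionMatrix, gapOpen, gapExtend)
  }
  final <- merged[[length(merged)]]
  final <- final[names(seqs), , drop = FALSE] # restore input order
  new("SeqAlignment", rows = matrixToRows(final, rownames(final)))
}

#' Align a sequence to a profile
#'
#' Global profile-to-sequence alignment under the profile's column scores
#' and gap penalties, the in-package analog of aligning a hit back to the
#' model that found it. The returned row lives in profile coordinates:
#' one character per profile column (residue or `-`), with residues that
#' fall between columns reported separately as insertions.
#'
#' @param profile a [ProfileModel-class].
#' @param seq non-empty residue string.
#' @return list with `row` (width = profile columns), `score` (bits),
#'   `insertions` (data.frame afterColumn/residues) and `a2m` (row with
#'   insertions as lowercase).
#' @export
alignToProfile <- function(profile, seq) {
  if (!nzchar(seq)) stop("sequence must be non-empty")
  checkResidues(seq, "sequence")
  codes <- aaCodes(seq)
  n <- ncol(profile@matchScores)
  S <- matrix(0, n, length(codes))
  ok <- !is.na(codes)
  S[, ok] <- t(profile@matchScores)[, codes[ok], drop = FALSE]
  res <- cpp_affine_global(S, profile@gapOpen, profile@gapExtend)
  chars <- strsplit(seq, "")[[1]]
  row <- character(n)
  ins <- list()
  i <- 0L; j <- 0L
  pending <- character(0)
  for (op in res$ops) {
    if (op == 0L) {
      i <- i + 1L; j <- j + 1L
      row[i] <- chars[j]
    } else if (op == 1L) {
      i <- i + 1L
      row[i] <- "-"
    } else {
      j <- j + 1L
      ins[[length(ins) + 1L]] <- c(i, chars[j])
    }
  }
  insDf <- if (length(ins)) {
    m <- do.call(rbind, ins)
    stats::aggregate(resid ~ afterColumn,
                     data.frame(afterColumn = as.integer(m[, 1]),
                                resid = m[, 2]),
                     FUN = paste, collapse = "")
  } else data.frame(afterColumn = integer(0), resid = character(0))
  a2m <- character(0)
  insMap <- stats::setNames(as.character(insDf$resid), insDf$afterColumn)
  if ("0" %in% names(insMap)) a2m <- tolower(insMap[["0"]])
  for (i in seq_len(n)) {
    a2m <- c(a2m, row[i])
    if (as.character(i) %in% names(insMap))
      a2m <- c(a2m, tolower(insMap[[as.character(i)]]))
  }
  list(row = paste(row, collapse = ""), score = res$score,
       insertions = insDf, a2m = paste(a2m, collapse = ""))
}

#' Trim alignment columns by occupancy
#'
#' Keeps exactly the columns whose non-gap fraction is at or above the
#' threshold (inclusive boundary), preserving column order and the full row
#' set. The 70% default follows standard occupancy trimming practice.
#'
#' @param alignment a [SeqAlignment-class].
#' @param minOccupancy fraction in (0, 1].
#' @return the trimmed [SeqAlignment-class]; kept source columns are in the
#'   `keptColumns` attribute.
#' @export
trimByOccupancy <- function(alignment, minOccupancy = 0.70) {
  if (minOccupancy <= 0 || minOccupancy > 1)
    stop("minOccupancy must be in (0, 1]")
  m <- gapMatrix(alignment@rows)
  occ <- colMeans(m != "-")
  keep <- which(occ >= minOccupancy - 1e-12)
  if (!length(keep)) stop("no column satisfies the occupancy threshold")
  out <- new("SeqAlignment",
             rows = matrixToRows(m[, keep, drop = FALSE],
                                 names(alignment@rows)))
  attr(out, "keptColumns") <- keep
  out
}
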