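# shared helpers: residue coding, seed splitting, tree plumbing

.aaLookup <- local({
  v <- rep(NA_integer_, 127)
  v[utf8ToInt(paste(AA_ALPHABET20, collapse = "")) -
      utf8ToInt("A") + 66] <- seq_len(20)
  v
})

# residue string -> integer codes 1..20 (NA for X, gaps, anything else)
aaCodes <- function(x) {
  ints <- utf8ToInt(x)
  idx <- ints - utf8ToInt("A") + 66L
  idx[idx < 1L | idx > 127L] <- 1L
  .aaLookup[idx]
}

# codes 1..20 (NA allowed) -> residue string with `na` for NA
aaString <- function(codes, na = "X") {
  ch <- c(AA_ALPHABET20, na)[ifelse(is.na(codes), 21L, codes)]
  paste(ch, collapse = "")
}

checkResidues <- function(x, what = "sequence", allowX = TRUE) {
  pat <- paste0("^[", paste(AA_ALPHABET20, collapse = ""),
                if (allowX) "X", "]+$")
  bad <- !grepl(pat, x)
  if (any(bad))
    stop(what, " contains illegal residue letters: ",
         paste(utils::head(unique(gsub(
           paste0("[", paste(AA_ALPHABET20, collapse = ""),
                  if (allowX) "X", "]"), "", x[bad])), 3), collapse = ""),
         call. = FALSE)
  invisible(TRUE)
}

#' Derive a stage-specific seed from a run seed
#'
#' All stochastic stages of the pipeline draw their own seed from the single
#' run seed with this mix, so stages stay reproducible independently of each
#' other. Results always fit in a 32-bit integer.
#'
#' @param seed integer run seed.
#' @param stage integer stage index (>= 0).
#' @return an integer seed.
#' @export
splitSeed <- function(seed, stage) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  x <- (s * 48271 + as.numeric(stage) * 16807) %% 2147483647
  x <- (x * 69621) %% 2147483647
  as.integer(x %% 2147483629 + 1)
}

# gapped string vector -> character matrix (rows = sequences)
gapMatrix <- function(rows) {
  m <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(m) <- names(rows)
  m
}

matrixToRows <- function(m, ids) {
  stats::setNames(apply(m, 1L, paste, collapse = ""), ids)
}

ungap <- function(x) gsub("-", "", x)

# ---------------------------------------------------------------------------
# tree plumbing

# rebuild an ape phylo from the engine's edge list (node ids preserved)
edgelistToPhylo <- function(edge, edgeLength, ntip, tipLabels) {
  adj <- vector("list", max(edge))
  for (e in seq_len(nrow(edge))) {
    a <- edge[e, 1]; b <- edge[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  build <- function(u, from) {
    kids <- adj[[u]]
    kids <- kids[kids[, 1] != from | is.na(from), , drop = FALSE]
    if (u <= ntip && nrow(kids) == 0)
      return(tipLabels[u])
    parts <- character(nrow(kids))
    for (i in seq_len(nrow(kids))) {
      v <- kids[i, 1]; e <- kids[i, 2]
      parts[i] <- paste0(build(v, u), ":", format(edgeLength[e], digits = 12))
    }
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- ntip + 1L
  txt <- paste0(build(root, NA), ";")
  ape::read.tree(text = txt)
}

# tip bipartition indicator rows for the splits of a (possibly
# multifurcating) tree, in the tip order `tipOrder`
constraintSplitMatrix <- function(constraint, tipOrder) {
  if (is.null(constraint)) return(matrix(0, 0, length(tipOrder)))
  pp <- ape::prop.part(constraint)
  labs <- attr(pp, "labels")
  out <- matrix(0, 0, length(tipOrder))
  for (part in pp) {
    tips <- labs[part]
    if (length(tips) <= 1L || length(tips) >= length(tipOrder) - 1L) next
    row <- as.numeric(tipOrder %in% tips)
    out <- rbind(out, row)
  }
  out
}

# does `tree` display every non-trivial split of `constraint`?
displaysConstraint <- function(tree, constraint) {
  want <- constraintSplitMatrix(constraint, tree$tip.label)
  if (nrow(want) == 0) return(TRUE)
  have <- ape::prop.part(ape::unroot(tree))
  labs <- attr(have, "labels")
  haveSets <- lapply(have, function(p) sort(labs[p]))
  n <- length(tree$tip.label)
  for (i in seq_len(nrow(want))) {
    tips <- sort(tree$tip.label[want[i, ] > 0.5])
    comp <- sort(setdiff(tree$tip.label, tips))
    hit <- any(vapply(haveSets, function(s)
      identical(s, tips) || identical(s, comp), logical(1)))
    if (!hit) return(FALSE)
  }
  TRUE
}

# alignment (SeqAlignment) -> list(codes = npat x ntip integer matrix with
# 0-based codes and -1 for gaps/X, weights, tipOrder)
compressPatterns <- function(alignment, tipOrder = NULL) {
  m <- gapMatrix(alignment@rows)
  rownames(m) <- names(alignment@rows)
  if (!is.null(tipOrder)) m <- m[tipOrder, , drop = FALSE]
  codes <- matrix(aaCodes(paste(t(m), collapse = ""))[seq_len(length(m))],
                  nrow = nrow(m), byrow = TRUE)
  codes[is.na(codes)] <- 0L
  codes <- codes - 1L # 0..19, -1 missing
  n <- nrow(codes)
  if (n <= 11L) {
    # numeric column key: exact for up to 11 rows (21^11 < 2^53)
    key <- colSums((codes + 1L) * 21^(seq_len(n) - 1L))
  } else {
    key <- apply(codes, 2L, paste, collapse = ",")
  }
  uk <- unique(key)
  idx <- match(key, uk)
  w <- as.numeric(tabulate(idx, nbins = length(uk)))
  first <- match(uk, key)
  list(codes = t(codes[, first, drop = FALSE]), weights = w,
       tipOrder = rownames(m))
}
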