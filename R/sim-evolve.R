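#' Simulate a Yule (pure-birth) tree
#'
#' @param nTips number of tips (>= 2).
#' @param birthRate speciation rate.
#' @param seed integer seed; identical inputs give identical trees.
#' @param tipLabels optional tip labels (default t1..tn from ape).
#' @return a rooted binary `phylo` with positive branch lengths.
#' @export
simulateYuleTree <- function(nTips, birthRate = 1.0, seed = 1L,
                             tipLabels = NULL) {
  if (nTips < 2) stop("nTips must be >= 2")
  if (birthRate <= 0) stop("birthRate must be positive")
  set.seed(seed)
  tr <- ape::rphylo(nTips, birth = birthRate, death = 0)
  if (!is.null(tipLabels)) {
    stopifnot(length(tipLabels) == nTips)
    tr$tip.label <- tipLabels
  }
  tr
}

# rescale a tree so its maximum root-to-tip path equals `height`
scaleTreeHeight <- function(tree, height) {
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h * height
  tree
}

# evolve a set of site codes along a single branch of length t
evolveBranch <- function(codes, t, eig, siteRates, seed) {
  set.seed(seed)
  if (t <= 0) return(codes)
  out <- codes
  for (r in unique(siteRates)) {
    idx <- which(siteRates == r)
    P <- transitionMatrix(eig, t * r)
    ps <- codes[idx]
    for (s in unique(ps)) {
      j <- idx[ps == s]
      out[j] <- sample.int(20L, length(j), replace = TRUE, prob = P[s, ])
    }
  }
  out
}

#' Evolve a gap-free alignment of tip sequences along a tree
#'
#' Sites evolve independently under the model's rate matrix; each site keeps
#' one gamma-category rate along the whole tree. This simulator doubles as
#' the parametric-bootstrap generator of the SOWH test.
#'
#' @param tree a `phylo` with branch lengths. Unrooted trees are evolved
#'   from their basal node, which is equivalent under the reversible model.
#' @param rootLength number of sites (>= 1).
#' @param model a [SubstitutionModel-class].
#' @param seed integer seed.
#' @param rateMultiplier multiplies all branch lengths (used for
#'   fast-evolving segments such as linkers).
#' @param rootCodes optional integer codes (1..20) of the root sequence;
#'   drawn from the equilibrium frequencies when NULL.
#' @param siteRates optional per-site rate vector; drawn from the model's
#'   discrete-gamma categories when NULL.
#' @param returnAncestors keep ancestral node sequences in the result.
#' @return a [SeqAlignment-class] of tip sequences (gap-free), with
#'   attributes `siteRates` and, if requested, `ancestralCodes` (matrix
#'   indexed by internal node id) and `tipCodes`.
#' @export
evolveAlignment <- function(tree, rootLength, model, seed,
                            rateMultiplier = 1, rootCodes = NULL,
                            siteRates = NULL, returnAncestors = FALSE) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have branch lengths")
  if (rootLength < 1) stop("rootLength must be >= 1")
  set.seed(seed)
  eig <- modelEigen(model)
  L <- as.integer(rootLength)
  if (is.null(siteRates))
    siteRates <- eig$rates[sample.int(length(eig$rates), L, replace = TRUE)]
  if (is.null(rootCodes))
    rootCodes <- sample.int(20L, L, replace = TRUE, prob = eig$pi)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- matrix(NA_integer_, nnode, L)
  root <- ntip + 1L
  seqs[root, ] <- rootCodes
  ord <- rev(ape::postorder(tree))
  uniqueRates <- unique(siteRates)
  rateIdx <- lapply(uniqueRates, function(r) which(siteRates == r))
  for (e in ord) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t <- tree$edge.length[e] * rateMultiplier
    if (t <= 0) {
      seqs[ch, ] <- seqs[par, ]
      next
    }
    child <- integer(L)
    for (k in seq_along(uniqueRates)) {
      idx <- rateIdx[[k]]
      P <- transitionMatrix(eig, t * uniqueRates[k])
      ps <- seqs[par, idx]
      for (s in unique(ps)) {
        j <- idx[ps == s]
        child[j] <- sample.int(20L, length(j), replace = TRUE, prob = P[s, ])
      }
    }
    seqs[ch, ] <- child
  }
  rows <- vapply(seq_len(ntip), function(i) aaString(seqs[i, ]), character(1))
  names(rows) <- tree$tip.label
  aln <- new("SeqAlignment", rows = rows)
  attr(aln, "siteRates") <- siteRates
  if (returnAncestors) {
    attr(aln, "ancestralCodes") <- seqs[(ntip + 1L):nnode, , drop = FALSE]
    attr(aln, "tipCodes") <- seqs[seq_len(ntip), , drop = FALSE]
  }
  aln
}
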