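# maximum-likelihood phylogenetics: pruning likelihood, NNI search,
# bootstrap, constrained search, the SOWH test and tree comparison

checkTipsMatchRows <- function(tree, alignment) {
  ids <- names(alignment@rows)
  if (!setequal(tree$tip.label, ids) ||
      length(tree$tip.label) != length(ids))
    stop("tree tips and alignment rows must match exactly")
}

prepEngineInput <- function(tree, alignment, model) {
  tree <- ape::unroot(tree)
  cp <- compressPatterns(alignment, tipOrder = tree$tip.label)
  list(tree = tree, codes = cp$codes, weights = cp$weights,
       eig = modelEigen(model))
}

# direct 2-taxon likelihood (the engine needs an internal node)
twoTaxonLoglik <- function(tree, alignment, model) {
  cp <- compressPatterns(alignment, tipOrder = tree$tip.label)
  eig <- modelEigen(model)
  t <- sum(tree$edge.length)
  site <- numeric(nrow(cp$codes))
  for (c in seq_along(eig$rates)) {
    P <- transitionMatrix(eig, t * eig$rates[c])
    for (p in seq_len(nrow(cp$codes))) {
      x <- cp$codes[p, 1] + 1L; y <- cp$codes[p, 2] + 1L
      l <- if (x < 1 && y < 1) 1
        else if (x < 1) eig$pi[y]
        else if (y < 1) eig$pi[x]
        else eig$pi[x] * P[x, y]
      site[p] <- site[p] + eig$rweights[c] * l
    }
  }
  sum(cp$weights * log(site))
}

#' Log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning with discrete-gamma rate mixing; gap and X characters
#' are treated as missing data (all-ones partials). The value is invariant
#' to re-rooting because the model is reversible.
#'
#' @param tree a `phylo` whose tips match the alignment rows; branch
#'   lengths required.
#' @param alignment a [SeqAlignment-class].
#' @param model a [SubstitutionModel-class].
#' @return the log-likelihood (numeric scalar).
#' @export
logLikelihood <- function(tree, alignment, model) {
  checkTipsMatchRows(tree, alignment)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have branch lengths")
  if (length(tree$tip.label) == 2L)
    return(twoTaxonLoglik(tree, alignment, model))
  inp <- prepEngineInput(tree, alignment, model)
  cpp_phylo_loglik(inp$tree$edge, inp$tree$edge.length,
                   length(inp$tree$tip.label), inp$codes, inp$weights,
                   inp$eig)
}

# Poisson-corrected pairwise distances for starting topologies
startingDistances <- function(alignment) {
  m <- gapMatrix(alignment@rows)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(alignment@rows),
                                       names(alignment@rows)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      p <- if (any(both)) mean(m[i, both] != m[j, both]) else 0.9
      p <- min(p, 0.93)
      d[i, j] <- d[j, i] <- -19 / 20 * log(1 - 20 / 19 * p)
    }
  }
  d
}

njStart <- function(alignment) {
  d <- startingDistances(alignment)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 1e-6] <- 1e-6
  ape::unroot(tr)
}

runEngineSearch <- function(start, alignment, model, constraint = NULL,
                            doNni = TRUE, maxNniRounds = 30L, tol = 1e-4) {
  start <- ape::unroot(start)
  inp <- prepEngineInput(start, alignment, model)
  splits <- constraintSplitMatrix(constraint, inp$tree$tip.label)
  res <- cpp_phylo_optimize(inp$tree$edge, inp$tree$edge.length,
                            length(inp$tree$tip.label), inp$codes,
                            inp$weights, inp$eig, doNni, splits,
                            as.integer(maxNniRounds), tol)
  tr <- edgelistToPhylo(res$edge, res$edge_length,
                        length(inp$tree$tip.label), inp$tree$tip.label)
  attr(tr, "logLik") <- res$logLik
  attr(tr, "converged") <- res$converged
  attr(tr, "nniMoves") <- res$nni_moves
  tr
}

#' Maximum-likelihood tree search
#'
#' Hill-climbing search: neighbor-joining start on Poisson-corrected
#' distances, Newton branch-length optimization, and NNI moves accepted
#' while they improve the log-likelihood by more than `tol`. The result is
#' a local optimum: no NNI move improves the likelihood by more than the
#' tolerance.
#'
#' @param alignment a [SeqAlignment-class] with >= 3 rows.
#' @param model a [SubstitutionModel-class].
#' @param seed integer seed (kept for interface stability; the search
#'   itself is deterministic).
#' @param startTree optional `phylo` to start from instead of the NJ tree.
#' @param tol minimal log-likelihood improvement for accepting a move.
#' @param maxNniRounds cap on NNI rounds.
#' @return an unrooted `phylo` with optimized branch lengths; attributes
#'   `logLik`, `converged`, `nniMoves`.
#' @export
mlTreeSearch <- function(alignment, model, seed = 1L, startTree = NULL,
                         tol = 1e-4, maxNniRounds = 30L) {
  if (length(alignment@rows) < 3L)
    stop("tree search needs at least 3 sequences")
  start <- if (is.null(startTree)) njStart(alignment) else startTree
  runEngineSearch(start, alignment, model, NULL, TRUE, maxNniRounds, tol)
}

# resolve a (possibly multifurcating) constraint into a data-informed start
# tree: polytomies are resolved by neighbor joining on average between-group
# distances, so the constrained search starts near a sensible optimum
constraintStart <- function(alignment, constraint) {
  ids <- names(alignment@rows)
  extra <- setdiff(constraint$tip.label, ids)
  if (length(extra))
    stop("constraint tips absent from the alignment: ",
         paste(extra, collapse = ", "))
  d <- startingDistances(alignment)
  njFragment <- function(groups) {
    # groups: list of list(tips=..., frag=newick fragment)
    k <- length(groups)
    if (k == 1L) return(groups[[1]]$frag)
    if (k == 2L)
      return(paste0("(", groups[[1]]$frag, ",", groups[[2]]$frag, ")"))
    D <- matrix(0, k, k, dimnames = list(paste0("ZZG", seq_len(k)),
                                         paste0("ZZG", seq_len(k))))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      D[i, j] <- D[j, i] <- mean(d[groups[[i]]$tips, groups[[j]]$tips])
    tr <- ape::nj(stats::as.dist(D))
    tr$edge.length <- NULL
    txt <- sub(";$", "", ape::write.tree(tr))
    for (i in seq_len(k))
      txt <- sub(paste0("ZZG", i, "(?![0-9])"), groups[[i]]$frag, txt,
                 perl = TRUE)
    txt
  }
  tipsetFragment <- function(tips) {
    if (length(tips) == 1L) return(list(tips = tips, frag = tips))
    njFrag <- njFragment(lapply(tips, function(t_)
      list(tips = t_, frag = t_)))
    list(tips = tips, frag = njFrag)
  }
  ntipC <- length(constraint$tip.label)
  resolveNode <- function(node) {
    if (node <= ntipC)
      return(list(tips = constraint$tip.label[node],
                  frag = constraint$tip.label[node]))
    kids <- constraint$edge[constraint$edge[, 1] == node, 2]
    groups <- lapply(kids, resolveNode)
    list(tips = unlist(lapply(groups, `[[`, "tips")),
         frag = njFragment(groups))
  }
  rootGroups <- lapply(constraint$edge[
    constraint$edge[, 1] == ntipC + 1L, 2], resolveNode)
  free <- setdiff(ids, constraint$tip.label)
  rootGroups <- c(rootGroups, lapply(free, tipsetFragment))
  tr <- ape::read.tree(text = paste0(njFragment(rootGroups), ";"))
  tr <- ape::multi2di(tr, random = FALSE)
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  ape::unroot(tr)
}

# rebuild a constraint-compliant tree that preserves the within-group
# structure of `guide`: each top-level constraint clade keeps its induced
# guide subtree, and the groups are joined by NJ on average distances
constraintRepairedStart <- function(alignment, constraint, guide) {
  d <- startingDistances(alignment)
  ids <- names(alignment@rows)
  frag <- function(tips) {
    if (length(tips) == 1L) return(tips)
    sub <- ape::keep.tip(guide, tips)
    sub$edge.length <- NULL
    sub$node.label <- NULL
    sub(";$", "", ape::write.tree(sub))
  }
  ntipC <- length(constraint$tip.label)
  kids <- constraint$edge[constraint$edge[, 1] == ntipC + 1L, 2]
  groups <- lapply(kids, function(node) {
    tips <- if (node <= ntipC) constraint$tip.label[node]
      else constraint$tip.label[
        phangorn::Descendants(constraint, node, "tips")[[1]]]
    list(tips = tips, frag = frag(tips))
  })
  free <- setdiff(ids, constraint$tip.label)
  groups <- c(groups, lapply(free, function(t_) list(tips = t_, frag = t_)))
  k <- length(groups)
  txt <- if (k == 1L) groups[[1]]$frag
  else if (k == 2L) paste0("(", groups[[1]]$frag, ",", groups[[2]]$frag, ")")
  else {
    D <- matrix(0, k, k, dimnames = list(paste0("ZZG", seq_len(k)),
                                         paste0("ZZG", seq_len(k))))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      D[i, j] <- D[j, i] <- mean(d[groups[[i]]$tips, groups[[j]]$tips])
    tr <- ape::nj(stats::as.dist(D))
    tr$edge.length <- NULL
    out <- sub(";$", "", ape::write.tree(tr))
    for (i in seq_len(k))
      out <- sub(paste0("ZZG", i, "(?![0-9])"), groups[[i]]$frag, out,
                 perl = TRUE)
    out
  }
  tr <- ape::read.tree(text = paste0(txt, ";"))
  tr <- ape::multi2di(tr, random = FALSE)
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  ape::unroot(tr)
}

#' Maximum-likelihood search under a topology constraint
#'
#' Every bipartition of the constraint tree must be present in the result;
#' NNI moves that would remove a constrained bipartition are rejected. A
#' star constraint is vacuous and reproduces the unconstrained search; a
#' fully resolved constraint leaves only branch lengths free. The search is
#' run from a data-informed constraint resolution and from any
#' `extraStarts` (which must display the constraint); the best optimum is
#' returned, which protects the SOWH statistic from one bad hill-climb.
#'
#' @inheritParams mlTreeSearch
#' @param constraint a `phylo` (possibly multifurcating) whose tip set is a
#'   subset of the alignment rows.
#' @param extraStarts optional list of additional starting trees.
#' @return as [mlTreeSearch()].
#' @export
constrainedMlSearch <- function(alignment, model, constraint, seed = 1L,
                                tol = 1e-4, maxNniRounds = 30L,
                                extraStarts = list()) {
  if (length(alignment@rows) < 3L)
    stop("tree search needs at least 3 sequences")
  starts <- c(list(constraintStart(alignment, constraint)), extraStarts)
  if (length(starts) > 1L) {
    # screen starts by branch-length optimization alone; the NNI search
    # runs once, from the best-scoring start
    screened <- vapply(starts, function(s)
      attr(runEngineSearch(s, alignment, model, constraint, doNni = FALSE),
           "logLik"), numeric(1))
    starts <- starts[order(-screened)[1]]
  }
  best <- NULL
  for (start in starts) {
    res <- runEngineSearch(start, alignment, model, constraint, TRUE,
                           maxNniRounds, tol)
    if (is.null(best) || attr(res, "logLik") > attr(best, "logLik"))
      best <- res
  }
  if (!displaysConstraint(best, constraint))
    stop("internal error: constrained search lost a constrained bipartition")
  best
}

#' Nonparametric bootstrap support values
#'
#' Site-resampled replicates, each analyzed with the full tree search;
#' support of each internal edge of the best tree is the percentage of
#' replicate trees containing that bipartition.
#'
#' @inheritParams mlTreeSearch
#' @param nReps number of bootstrap replicates (the conventional default
#'   is 1000; reduce for quick looks).
#' @return the best tree with `node.label` set to support percentages and a
#'   `bootstrapTrees` attribute.
#' @export
bootstrapSupport <- function(alignment, model, nReps = 1000L, seed = 1L) {
  if (nReps < 1L) stop("nReps must be >= 1")
  best <- mlTreeSearch(alignment, model, seed)
  m <- gapMatrix(alignment@rows)
  L <- ncol(m)
  reps <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    set.seed(splitSeed(seed, 1000L + r))
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- new("SeqAlignment",
                   rows = matrixToRows(m[, cols, drop = FALSE],
                                       names(alignment@rows)))
    reps[[r]] <- mlTreeSearch(rep_aln, model, splitSeed(seed, 2000L + r))
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(best, reps, rooted = FALSE)
  counts[is.na(counts)] <- nReps
  best$node.label <- round(100 * counts / nReps, 1)
  attr(best, "bootstrapTrees") <- reps
  best
}

#' SOWH parametric-bootstrap topology test
#'
#' Tests whether the data reject a topological constraint. The statistic is
#' `delta = lnL(unconstrained ML) - lnL(constrained ML)` (never negative; if
#' the free search lands below the constrained optimum it is restarted from
#' the constrained topology). The null distribution comes from `nSims`
#' alignments simulated on the constrained ML tree under the fitted model
#' and re-analyzed identically. The p-value uses the add-one rule
#' `(1 + #\{null >= observed\}) / (1 + nSims)`, so it is never exactly 0.
#'
#' @inheritParams constrainedMlSearch
#' @param nSims number of parametric-bootstrap simulations (>= 1).
#' @return a [SOWHResult-class].
#' @export
sowhTest <- function(alignment, model, constraint, nSims = 100L, seed = 1L) {
  if (nSims < 1L) stop("nSims must be >= 1")
  L <- nColumns(alignment)
  deltaOf <- function(aln, sd, conStarts = list(), useRepair = TRUE) {
    unc <- mlTreeSearch(aln, model, splitSeed(sd, 2L))
    if (displaysConstraint(unc, constraint)) {
      # the free optimum already satisfies the constraint: the constrained
      # optimum is the same tree and the statistic is zero
      con <- runEngineSearch(unc, aln, model, constraint, TRUE, 30L, 1e-4)
      return(list(delta = max(0, attr(unc, "logLik") - attr(con, "logLik")),
                  tree = con, ok = isTRUE(attr(unc, "converged"))))
    }
    if (useRepair) {
      repair <- tryCatch(constraintRepairedStart(aln, constraint, unc),
                         error = function(e) NULL)
      if (!is.null(repair)) conStarts <- c(conStarts, list(repair))
    }
    con <- constrainedMlSearch(aln, model, constraint, splitSeed(sd, 1L),
                               extraStarts = conStarts)
    if (attr(unc, "logLik") < attr(con, "logLik"))
      unc <- mlTreeSearch(aln, model, splitSeed(sd, 3L), startTree = con)
    list(delta = max(0, attr(unc, "logLik") - attr(con, "logLik")),
         tree = con,
         ok = isTRUE(attr(unc, "converged")) && isTRUE(attr(con, "converged")))
  }
  obs <- deltaOf(alignment, splitSeed(seed, 11L))
  nullDeltas <- numeric(nSims)
  okCount <- 0L
  for (i in seq_len(nSims)) {
    sim <- evolveAlignment(obs$tree, L, model, splitSeed(seed, 5000L + i))
    # the generating tree is a legitimate extra start: it displays the
    # constraint by construction and guards the null statistic against a
    # stray local optimum (and makes the repair start redundant here)
    d <- deltaOf(sim, splitSeed(seed, 6000L + i), conStarts = list(obs$tree),
                 useRepair = FALSE)
    nullDeltas[i] <- d$delta
    okCount <- okCount + as.integer(d$ok)
  }
  p <- (1 + sum(nullDeltas >= obs$delta)) / (1 + nSims)
  new("SOWHResult", observedDelta = obs$delta, nullDeltas = nullDeltas,
      pValue = p, nSims = as.integer(nSims),
      convergedSims = okCount)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions; both trees must
#' have identical tip sets.
#'
#' @param t1,t2 `phylo` objects.
#' @return a non-negative integer, at most 2(n-3) for binary trees.
#' @export
rfDistance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label))
    stop("trees must have identical tip sets")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

cladeTipSets <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  lapply(pp, function(p) sort(labs[p]))
}

#' Per-clade Jaccard similarity between two trees
#'
#' For each internal node of `t1`, the maximal Jaccard index
#' `|A ∩ B| / |A ∪ B|` between its descendant tip set and any internal
#' clade of `t2`. Identical trees score 1 at every node.
#'
#' @param t1,t2 `phylo` objects with overlapping tip sets.
#' @return numeric vector of scores in (0, 1], one per internal node of
#'   `t1`, named by node id.
#' @export
jaccardTreeSimilarity <- function(t1, t2) {
  if (!length(intersect(t1$tip.label, t2$tip.label)))
    stop("trees share no tips")
  c1 <- cladeTipSets(t1)
  c2 <- cladeTipSets(t2)
  scores <- vapply(c1, function(a) {
    max(vapply(c2, function(b)
      length(intersect(a, b)) / length(union(a, b)), numeric(1)))
  }, numeric(1))
  names(scores) <- length(t1$tip.label) + seq_along(scores)
  scores
}

#' Fit the gamma shape on a fixed topology by golden-section search
#'
#' @param alignment a [SeqAlignment-class].
#' @param model base model; its shape is replaced.
#' @param tree optional topology (default: NJ start).
#' @param interval search interval for the shape.
#' @return the model with the fitted `gammaShape`.
#' @export
fitGammaShape <- function(alignment, model, tree = NULL,
                          interval = c(0.2, 5)) {
  if (is.null(tree)) tree <- njStart(alignment)
  f <- function(shape) {
    m <- model
    m@gammaShape <- shape
    -attr(runEngineSearch(tree, alignment, m, doNni = FALSE), "logLik")
  }
  opt <- stats::optimize(f, interval, tol = 0.02)
  model@gammaShape <- opt$minimum
  model
}
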