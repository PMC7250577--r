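# Independent oracles used by the acceptance tests. They are deliberately
# naive (exhaustive enumeration) and share no code with the implementations
# they check.

# exhaustive affine-gap global alignment score: enumerates every alignment
# recursively; gap of length L costs open + extend * L
oracleGlobalScore <- function(a, b, sub, gapOpen, gapExtend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    # state: 0 = start/after match, 1 = in gap consuming a, 2 = in gap in b
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, sub[ca[i], cb[j]] + rec(i + 1, j + 1, 0))
    }
    if (i <= length(ca)) {
      cost <- if (state == 1) gapExtend else gapOpen + gapExtend
      best <- max(best, -cost + rec(i + 1, j, 1))
    }
    if (j <= length(cb)) {
      cost <- if (state == 2) gapExtend else gapOpen + gapExtend
      best <- max(best, -cost + rec(i, j + 1, 2))
    }
    best
  }
  rec(1, 1, 0)
}

# exhaustive gapless local profile-segment score: best sum of matched
# consecutive profile columns x sequence residues over all offsets/lengths
oracleLocalGaplessScore <- function(matchScores, seq) {
  codes <- match(strsplit(seq, "")[[1]], AA_ALPHABET20)
  n <- ncol(matchScores)
  m <- length(codes)
  best <- 0
  for (pi in seq_len(n)) for (si in seq_len(m)) {
    s <- 0
    k <- 0
    while (pi + k <= n && si + k <= m) {
      sc <- if (is.na(codes[si + k])) 0 else matchScores[codes[si + k], pi + k]
      s <- s + sc
      best <- max(best, s)
      k <- k + 1
    }
  }
  best
}

# exhaustive pruning oracle: sums over all internal-node state assignments;
# transition probabilities via matrix exponentials (independent of the
# engine's spectral path)
oracleLogLik <- function(tree, aln, mod) {
  Q <- chimeraTrace:::modelQ(mod)
  rates <- chimeraTrace:::gammaCategoryRates(mod@gammaShape,
                                             mod@nRateCategories)
  eig <- list(pi = unname(mod@equilibriumFreqs), rates = rates,
              rweights = rep(1 / length(rates), length(rates)))
  ntip <- length(tree$tip.label)
  m <- chimeraTrace:::gapMatrix(aln@rows)
  m <- m[tree$tip.label, , drop = FALSE]
  codes <- matrix(match(m, AA_ALPHABET20), nrow = nrow(m))
  nnode <- ntip + tree$Nnode
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    lapply(eig$rates, function(r)
      as.matrix(Matrix::expm(Q * tree$edge.length[e] * r))))
  intn <- (ntip + 1):nnode
  grid <- as.matrix(do.call(expand.grid, rep(list(1:20), length(intn))))
  total <- 0
  for (site in seq_len(ncol(codes))) {
    sl <- 0
    for (ci in seq_along(eig$rates)) {
      pvec <- eig$pi[grid[, 1]]
      for (e in seq_len(nrow(tree$edge))) {
        an <- tree$edge[e, 1]; bn <- tree$edge[e, 2]
        aidx <- if (an <= ntip) rep(codes[an, site], nrow(grid))
          else grid[, an - ntip]
        bidx <- if (bn <= ntip) rep(codes[bn, site], nrow(grid))
          else grid[, bn - ntip]
        if (bn <= ntip && is.na(codes[bn, site])) next # missing tip data
        pvec <- pvec * Ps[[e]][[ci]][cbind(aidx, bidx)]
      }
      sl <- sl + eig$rweights[ci] * sum(pvec)
    }
    total <- total + log(sl)
  }
  total
}

# brute-force Robinson-Foulds: compare canonicalized non-trivial
# bipartitions directly
oracleRF <- function(t1, t2) {
  splitsOf <- function(tr) {
    tr <- ape::unroot(tr)
    ntip <- length(tr$tip.label)
    out <- character(0)
    for (node in (ntip + 2):(ntip + tr$Nnode)) {
      tips <- sort(tr$tip.label[phangorn::Descendants(tr, node, "tips")[[1]]])
      if (length(tips) <= 1 || length(tips) >= ntip - 1) next
      comp <- sort(setdiff(tr$tip.label, tips))
      key <- if (tips[1] < comp[1]) paste(tips, collapse = "|")
        else paste(comp, collapse = "|")
      out <- c(out, key)
    }
    unique(out)
  }
  s1 <- splitsOf(t1); s2 <- splitsOf(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# brute-force per-clade Jaccard: all clade pairs
oracleJaccard <- function(t1, t2) {
  sets1 <- chimeraTrace:::cladeTipSets(t1)
  sets2 <- chimeraTrace:::cladeTipSets(t2)
  vapply(sets1, function(a)
    max(vapply(sets2, function(b)
      length(intersect(a, b)) / length(union(a, b)), numeric(1))),
    numeric(1))
}

# small random gap-free alignment for likelihood fixtures
randomAlignment <- function(ntip, nsites, seed, withGaps = FALSE) {
  set.seed(seed)
  rows <- vapply(seq_len(ntip), function(i) {
    ch <- sample(AA_ALPHABET20, nsites, replace = TRUE)
    if (withGaps) {
      gapAt <- stats::runif(nsites) < 0.15
      ch[gapAt] <- "-"
    }
    paste(ch, collapse = "")
  }, character(1))
  names(rows) <- paste0("t", seq_len(ntip))
  new("SeqAlignment", rows = rows)
}
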