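# likelihood engine, tree search, bootstrap, constraints, tree comparison

test_that("pruning log-likelihood matches hand-computable cases", {
  mod <- poissonModel()
  # two identical tips at zero distance: lnL = L * ln(1/20)
  t2 <- ape::read.tree(text = "(a:0,b:0);")
  a2 <- new("SeqAlignment", rows = c(a = "ACDE", b = "ACDE"))
  expect_equal(logLikelihood(t2, a2, mod), 4 * log(1 / 20), tolerance = 1e-10)
  # two tips, one site, differing residues at distance t (closed form)
  t <- 0.7
  t2b <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t / 3, 2 * t / 3))
  a2b <- new("SeqAlignment", rows = c(a = "A", b = "C"))
  pDiffOne <- (1 / 20) * (1 - exp(-20 * t / 19)) # P(one specific other state)
  expect_equal(logLikelihood(t2b, a2b, mod), log((1 / 20) * pDiffOne),
               tolerance = 1e-10)
  expect_error(logLikelihood(t2, new("SeqAlignment", rows = c(a = "A", x = "C")),
                             mod), "match")
})

test_that("pruning equals the exhaustive-state oracle on small fixtures", {
  skip_if_not_installed("Matrix")
  cases <- list(
    list(ntip = 3, nsites = 5, mod = poissonModel(), gaps = FALSE),
    list(ntip = 4, nsites = 8, mod = poissonModel(), gaps = TRUE),
    list(ntip = 4, nsites = 6, mod = lgModel(gammaShape = 0.6,
                                             nRateCategories = 3), gaps = FALSE),
    list(ntip = 5, nsites = 10, mod = lgModel(gammaShape = 1.2,
                                              nRateCategories = 2), gaps = TRUE))
  for (cs in cases) {
    tr <- ape::unroot(simulateYuleTree(cs$ntip, 1, cs$ntip * 3))
    aln <- randomAlignment(cs$ntip, cs$nsites, cs$ntip + 100,
                           withGaps = cs$gaps)
    names(aln@rows) <- tr$tip.label
    got <- logLikelihood(tr, aln, cs$mod)
    want <- oracleLogLik(tr, aln, cs$mod)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("log-likelihood is invariant under re-rooting", {
  mod <- lgModel(gammaShape = 1, nRateCategories = 2)
  tr <- simulateYuleTree(6, 1, 44)
  aln <- evolveAlignment(tr, 40, mod, 45)
  base <- logLikelihood(tr, aln, mod)
  for (og in c("t1", "t3", "t5")) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(logLikelihood(rerooted, aln, mod), base, tolerance = 1e-8)
  }
})

test_that("ML search optimizes and recovers strong signal", {
  mod <- poissonModel()
  # 3 taxa: the unique unrooted topology with optimized branch lengths
  tr3 <- chimeraTrace:::scaleTreeHeight(simulateYuleTree(3, 1, 5), 0.4)
  a3 <- evolveAlignment(tr3, 200, mod, 6)
  fit3 <- mlTreeSearch(a3, mod)
  expect_equal(length(fit3$tip.label), 3L)
  expect_error(mlTreeSearch(new("SeqAlignment", rows = c(a = "A", b = "C")),
                            mod), "at least 3")
  # hill-climb contract: final lnL is at least the start tree lnL
  tr <- chimeraTrace:::scaleTreeHeight(simulateYuleTree(6, 1, 8), 0.5)
  aln <- evolveAlignment(tr, 300, mod, 9)
  start <- chimeraTrace:::njStart(aln)
  fit <- mlTreeSearch(aln, mod, startTree = start)
  expect_gte(attr(fit, "logLik"), logLikelihood(start, aln, mod))
  # 4-taxon strong signal: recovers the generating topology, checked
  # against an exhaustive scan of all 3 unrooted topologies
  tr4 <- ape::read.tree(text = "((a:0.1,b:0.1):0.15,(c:0.1,d:0.1):0.15);")
  a4 <- evolveAlignment(tr4, 500, mod, 10)
  fit4 <- mlTreeSearch(a4, mod)
  topos <- phangorn::allTrees(4, tip.label = c("a", "b", "c", "d"))
  lls <- vapply(topos, function(tt) {
    tt$edge.length <- rep(0.1, nrow(tt$edge))
    attr(chimeraTrace:::runEngineSearch(tt, a4, mod, doNni = FALSE), "logLik")
  }, numeric(1))
  expect_equal(attr(fit4, "logLik"), max(lls), tolerance = 1e-3)
  expect_equal(rfDistance(fit4, tr4), 0)
})

test_that("trees inferred from 500-site alignments recover the true 6-taxon topology", {
  # internal edges are floored at 0.03 substitutions/site: an edge carrying
  # no expected substitutions is unidentifiable at any alignment length
  mod <- poissonModel()
  okCount <- 0
  for (seed in 1:20) {
    tr <- chimeraTrace:::scaleTreeHeight(simulateYuleTree(6, 1, seed), 0.5)
    tr$edge.length <- pmax(tr$edge.length, 0.03)
    aln <- evolveAlignment(tr, 500, mod, seed + 200)
    fit <- mlTreeSearch(aln, mod)
    okCount <- okCount + (rfDistance(fit, tr) == 0)
  }
  expect_gte(okCount / 20, 0.9)
})

test_that("constrained search honors constraints without beating the free search", {
  mod <- poissonModel()
  tr <- chimeraTrace:::scaleTreeHeight(simulateYuleTree(6, 1, 31), 0.5)
  aln <- evolveAlignment(tr, 250, mod, 32)
  free <- mlTreeSearch(aln, mod)
  # star constraint is vacuous: same optimum as the unconstrained search
  star <- ape::read.tree(text = paste0(
    "(", paste(tr$tip.label, collapse = ","), ");"))
  fitStar <- constrainedMlSearch(aln, mod, star)
  expect_equal(attr(fitStar, "logLik"), attr(free, "logLik"),
               tolerance = 1e-2)
  # fully resolved constraint: topology equals the constraint
  fitFull <- constrainedMlSearch(aln, mod, ape::unroot(tr))
  expect_equal(rfDistance(fitFull, tr), 0)
  expect_lte(attr(fitFull, "logLik"), attr(free, "logLik") + 1e-4)
  # a wrong-clade constraint is displayed and cannot beat the free optimum
  wrong <- ape::read.tree(text = paste0(
    "((", tr$tip.label[1], ",", tr$tip.label[4], "),",
    paste(tr$tip.label[c(2, 3, 5, 6)], collapse = ","), ");"))
  fitW <- constrainedMlSearch(aln, mod, wrong)
  expect_true(chimeraTrace:::displaysConstraint(fitW, wrong))
  expect_lte(attr(fitW, "logLik"), attr(free, "logLik") + 1e-4)
})

test_that("bootstrap support is bounded, deterministic, and unanimous when it should be", {
  mod <- poissonModel()
  # alignment where every site supports the same 4-taxon split: two pairs
  # of identical sequences, pairs far apart
  rows <- c(a = "AAAAAAAAAACCCCCCCCCC", b = "AAAAAAAAAACCCCCCCCCC",
            c = "WWWWWWWWWWHHHHHHHHHH", d = "WWWWWWWWWWHHHHHHHHHH")
  aln <- new("SeqAlignment", rows = rows)
  bs <- bootstrapSupport(aln, mod, nReps = 30, seed = 2)
  expect_true(all(bs$node.label >= 0 & bs$node.label <= 100))
  inner <- which(!is.na(bs$node.label))
  expect_true(all(bs$node.label == 100))
  bs2 <- bootstrapSupport(aln, mod, nReps = 30, seed = 2)
  expect_identical(bs$node.label, bs2$node.label)
})

test_that("Robinson-Foulds distance matches the brute-force bipartition oracle", {
  expect_equal(rfDistance(simulateYuleTree(6, 1, 3), simulateYuleTree(6, 1, 3)), 0)
  set.seed(12)
  for (i in 1:10) {
    t1 <- ape::rtree(6)
    t2 <- ape::rtree(6)
    got <- rfDistance(t1, t2)
    expect_equal(got, oracleRF(t1, t2))
    expect_equal(got, rfDistance(t2, t1)) # symmetry
    expect_lte(got, 2 * (6 - 3)) # bound for binary trees
  }
  expect_error(rfDistance(ape::rtree(4), ape::rtree(5)), "identical tip sets")
})

test_that("Jaccard tree similarity matches the all-pairs clade oracle", {
  t1 <- simulateYuleTree(5, 1, 9)
  expect_true(all(jaccardTreeSimilarity(t1, t1) == 1))
  set.seed(21)
  for (i in 1:8) {
    a <- ape::rtree(5); b <- ape::rtree(5)
    got <- jaccardTreeSimilarity(a, b)
    expect_equal(unname(got), oracleJaccard(a, b))
    expect_true(all(got > 0 & got <= 1))
  }
  d1 <- ape::rtree(4)
  d2 <- ape::rtree(4)
  d2$tip.label <- paste0("zz", d2$tip.label)
  expect_error(jaccardTreeSimilarity(d1, d2), "share no tips")
})

test_that("a satisfied constraint gives a null SOWH statistic and p near 1", {
  mod <- poissonModel()
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2,(e:0.1,f:0.1):0.2);")
  aln <- evolveAlignment(tr, 400, mod, 55)
  constraint <- ape::read.tree(text = "((a,b),c,d,e,f);")
  sw <- sowhTest(aln, mod, constraint, nSims = 20, seed = 56)
  expect_lte(sw@observedDelta, 0.1)
  expect_gte(sw@pValue, 0.5)
  expect_equal(sw@pValue,
               (1 + sum(sw@nullDeltas >= sw@observedDelta)) / (1 + 20))
})

test_that("a violated constraint with strong signal is rejected", {
  mod <- poissonModel()
  # true tree groups (a,b); constraint forces (a,c) monophyly
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.4,(c:0.05,d:0.05):0.4,(e:0.05,f:0.05):0.4);")
  aln <- evolveAlignment(tr, 400, mod, 57)
  constraint <- ape::read.tree(text = "((a,c),b,d,e,f);")
  sw <- sowhTest(aln, mod, constraint, nSims = 30, seed = 58)
  expect_gt(sw@observedDelta, 10)
  expect_lt(sw@pValue, 0.05)
})
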