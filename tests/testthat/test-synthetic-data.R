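# simulators: Yule trees, sequence evolution, scenario generation

test_that("Yule tree simulation meets its shape and determinism contracts", {
  expect_error(simulateYuleTree(1), ">= 2")
  t2 <- simulateYuleTree(2, 1, 5)
  expect_equal(length(t2$tip.label), 2L)
  expect_equal(t2$Nnode, 1L)
  t5 <- simulateYuleTree(5, 1, 5)
  expect_equal(length(t5$tip.label), 5L)
  expect_equal(t5$Nnode, 4L) # n - 1 internal nodes in a rooted binary tree
  expect_true(all(t5$edge.length > 0))
  expect_identical(ape::write.tree(simulateYuleTree(7, 2, 99)),
                   ape::write.tree(simulateYuleTree(7, 2, 99)))
})

test_that("zero branch lengths transmit the root sequence unchanged", {
  tr <- simulateYuleTree(4, 1, 3)
  tr$edge.length[] <- 0
  aln <- evolveAlignment(tr, 30, poissonModel(), 8)
  expect_equal(length(unique(aln@rows)), 1L)
  tr$edge.length <- NULL
  expect_error(evolveAlignment(tr, 30, poissonModel(), 8), "branch lengths")
})

test_that("two-taxon divergence matches the 20-state equal-rates closed form", {
  # P(differ) = (19/20) (1 - exp(-20 t / 19)) at total path length t
  t <- 0.4
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t / 2, t / 2))
  L <- 10000
  aln <- evolveAlignment(tr, L, poissonModel(), 123)
  pObs <- mean(strsplit(aln@rows[["a"]], "")[[1]] !=
                 strsplit(aln@rows[["b"]], "")[[1]])
  pExp <- 19 / 20 * (1 - exp(-20 * t / 19))
  se <- sqrt(pExp * (1 - pExp) / L)
  expect_lt(abs(pObs - pExp), 3 * se)
})

test_that("sequence evolution is reproducible for a fixed seed", {
  tr <- simulateYuleTree(5, 1, 4)
  a1 <- evolveAlignment(tr, 25, lgModel(), 77)
  a2 <- evolveAlignment(tr, 25, lgModel(), 77)
  expect_identical(a1@rows, a2@rows)
  a3 <- evolveAlignment(tr, 25, lgModel(), 78)
  expect_false(identical(a1@rows, a3@rows))
})

test_that("scenario configs are validated", {
  expect_error(scenarioConfig(scenarioKind = "chimera", fusionCladeSize = 2),
               "fusionCladeSize >= 3")
  expect_error(scenarioConfig(scenarioKind = "banana"), "chimera")
  expect_error(scenarioConfig(nEukaryoteTaxa = 3, fusionCladeSize = 4),
               "cannot exceed")
})

test_that("chimera scenarios have the promised structure", {
  sc <- generateScenario(scenarioConfig(seed = 21, backgroundCount = 5L))
  db <- sc$db
  # taxonomy covers every record exactly once
  expect_setequal(db@taxonomy$id, seqIds(db))
  expect_equal(nrow(db@taxonomy), length(db))
  seqs <- dbSequences(db)
  # every fusion protein: domain A strictly N-terminal to domain B
  for (id in sc$truth$fusionMemberIds) {
    sp <- sc$truth$domainSpans[[id]]
    expect_lt(sp$domainA[2], sp$domainB[1])
    expect_equal(sp$domainB[2], nchar(seqs[[id]]))
  }
  # six-frame translation of each transcript recovers the protein exactly
  for (i in seq_along(sc$transcripts)) {
    id <- sub("_tx$", "", names(sc$transcripts)[i])
    orf <- longestOrf(sixFrameTranslate(sc$transcripts[[i]]))
    expect_identical(orf$orf, seqs[[id]])
  }
  # seed alignments hold true domain segments of the first orthologs
  expect_equal(nColumns(sc$seedA), 80L)
  # ground truth tips exist in the taxonomy
  expect_true(all(sc$truth$fusionMemberIds %in% db@taxonomy$id))
  # background_count = 0 drops background records only
  sc0 <- generateScenario(scenarioConfig(seed = 21, backgroundCount = 0L))
  expect_false(any(sc0$db@taxonomy$category == "background"))
})

test_that("fusion domain B segments are closest to bacteria in chimera scenarios", {
  # mean pairwise identity of fusion B segments: nearest bacterial family
  # member beats every eukaryotic family-A member (5 seeds)
  for (seed in 1:5) {
    sc <- generateScenario(scenarioConfig(seed = seed, backgroundCount = 0L))
    seqs <- dbSequences(sc$db)
    tx <- sc$db@taxonomy
    bacIds <- tx$id[tx$domain_of_life == "Bacteria" & tx$category == "familyB"]
    famAIds <- tx$id[tx$category == "familyA"]
    idTo <- function(seg, ids) vapply(ids, function(i) {
      al <- globalAlign(seg, seqs[[i]])
      percentIdentity(al$alignedA, al$alignedB)
    }, numeric(1))
    for (id in sc$truth$fusionMemberIds) {
      sp <- sc$truth$domainSpans[[id]]
      segB <- substr(seqs[[id]], sp$domainB[1], sp$domainB[2])
      expect_gt(max(idTo(segB, bacIds)), max(idTo(segB, famAIds)))
    }
  }
})

test_that("linker columns evolve faster than domain columns", {
  # substitutions relative to the root sequence, averaged over 5 seeds
  linkRates <- domRates <- numeric(0)
  for (seed in 1:5) {
    sc <- generateScenario(scenarioConfig(seed = seed, backgroundCount = 0L))
    lk <- sc$truth$linker
    rootL <- strsplit(lk$root, "")[[1]]
    subsL <- vapply(lk$fullRows, function(r)
      mean(strsplit(r, "")[[1]] != rootL), numeric(1))
    fusA <- sc$truth$linker$fusionDomainA
    rootA <- chimeraTrace:::aaString(sc$truth$linker$rootCodesA)
    rootAch <- strsplit(rootA, "")[[1]]
    subsA <- vapply(fusA@rows, function(r)
      mean(strsplit(r, "")[[1]] != rootAch), numeric(1))
    linkRates <- c(linkRates, mean(subsL))
    domRates <- c(domRates, mean(subsA))
  }
  expect_gt(mean(linkRates), mean(domRates))
})
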