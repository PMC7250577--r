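# iterative two-domain ortholog discovery

test_that("architecture hits require both domains in order", {
  sc <- generateScenario(scenarioConfig(seed = 15, backgroundCount = 10L))
  pA <- calibrateEvalue(buildProfile(sc$seedA), sc$db, 120, seed = 1)
  pB <- calibrateEvalue(buildProfile(sc$seedB), sc$db, 120, seed = 2)
  hits <- findArchitectureHits(sc$db, pA, pB, 0.01)
  # only fusion proteins carry both domains
  expect_setequal(hits$target_id, sc$truth$fusionMemberIds)
  expect_true(all(hits$a_end < hits$b_start))
  # single-domain sequences (family A alone) are negative
  tx <- taxonomyTable(sc$db)
  expect_false(any(tx$category[match(hits$target_id, tx$id)] %in%
                     c("familyA", "familyB")))
  # linker spans fill the gap between the envelopes
  withLinker <- !is.na(hits$linker_start)
  expect_true(all(hits$linker_start[withLinker] ==
                    hits$a_end[withLinker] + 1L))
  expect_true(all(hits$linker_end[withLinker] ==
                    hits$b_start[withLinker] - 1L))
})

test_that("abutting domains are accepted with an empty linker", {
  # hand-built database: one two-domain protein with no linker, one with a
  # linker, one reversed-order protein
  set.seed(8)
  domA <- paste(sample(AA_ALPHABET20, 40, replace = TRUE), collapse = "")
  domB <- paste(sample(AA_ALPHABET20, 50, replace = TRUE), collapse = "")
  db <- taxSeqDB(
    c(abut = paste0(domA, domB),
      link = paste0(domA, "GGSGGSGGSG", domB),
      rev = paste0(domB, domA)),
    "Eukaryota", "focal")
  mk <- function(s) new("SeqAlignment", rows = c(x = s, y = s, z = s))
  pA <- calibrateEvalue(buildProfile(mk(domA)), db, 120, seed = 1)
  pB <- calibrateEvalue(buildProfile(mk(domB)), db, 120, seed = 2)
  hits <- findArchitectureHits(db, pA, pB, 0.01)
  expect_setequal(hits$target_id, c("abut", "link"))
  expect_true(is.na(hits$linker_start[hits$target_id == "abut"]))
  expect_equal(hits[hits$target_id == "link", "linker_start"], 41L)
  rej <- attr(hits, "rejected")
  expect_true("rev" %in% rej$target_id)
  # relaxing the order admits the reversed protein
  hits2 <- findArchitectureHits(db, pA, pB, 0.01, enforceOrder = FALSE)
  expect_true("rev" %in% hits2$target_id)
})

test_that("iterative discovery converges to the ground-truth fusion set", {
  # recovery >= 90% with zero false positives, five seeds; accepted ids
  # grow monotonically to a fixed point
  recovered <- fps <- numeric(0)
  for (seed in 1:5) {
    sc <- generateScenario(scenarioConfig(seed = seed))
    disc <- iterateDiscovery(sc$db, sc$seedA, sc$seedB, eThreshold = 0.01,
                             seed = splitSeed(seed, 7))
    expect_true(disc@converged)
    expect_true(all(diff(disc@log$n_accepted) >= 0))
    truth <- sc$truth$fusionMemberIds
    recovered <- c(recovered, mean(truth %in% disc@acceptedIds))
    fps <- c(fps, sum(!disc@acceptedIds %in% truth))
  }
  expect_gte(mean(recovered), 0.9)
  expect_equal(sum(fps), 0)
})

test_that("discovery state flags non-convergence at maxRounds", {
  sc <- generateScenario(scenarioConfig(seed = 16))
  disc1 <- iterateDiscovery(sc$db, sc$seedA, sc$seedB, maxRounds = 1L,
                            seed = 3)
  expect_false(disc1@converged) # round 1 added sequences
  expect_equal(disc1@round, 1L)
  # full run: fixed point confirmed by one extra round
  disc <- iterateDiscovery(sc$db, sc$seedA, sc$seedB, seed = 3)
  expect_true(disc@converged)
  expect_gte(disc@round, 2L)
})

test_that("discovery is invariant to database record order", {
  sc <- generateScenario(scenarioConfig(seed = 17, backgroundCount = 8L))
  ids <- seqIds(sc$db)
  set.seed(1)
  shuffled <- sc$db[sample(ids)]
  d1 <- iterateDiscovery(sc$db, sc$seedA, sc$seedB, seed = 5)
  d2 <- iterateDiscovery(shuffled, sc$seedA, sc$seedB, seed = 5)
  expect_identical(sort(d1@acceptedIds), sort(d2@acceptedIds))
})

test_that("null databases without fusion genes stay empty", {
  # family A and B present, but no two-domain protein: no architecture
  # hits at the stringent threshold (5 seeds)
  for (seed in 1:5) {
    sc <- generateScenario(scenarioConfig(seed = seed, backgroundCount = 6L))
    keep <- setdiff(seqIds(sc$db), sc$truth$fusionMemberIds)
    db <- sc$db[keep]
    disc <- iterateDiscovery(db, sc$seedA, sc$seedB, eThreshold = 0.01,
                             seed = splitSeed(seed, 9))
    expect_length(disc@acceptedIds, 0)
    expect_true(disc@converged)
  }
})

test_that("best-per-species deduplication keeps the lowest E-value", {
  hits <- data.frame(
    target_id = c("x1", "x2", "y1"),
    e_value = c(1e-30, 1e-10, 1e-5), stringsAsFactors = FALSE)
  species <- c(x1 = "spX", x2 = "spX", y1 = "spY")
  out <- dedupeBestPerSpecies(hits, species)
  expect_setequal(out$target_id, c("x1", "y1"))
  # all-distinct species: unchanged; empty input: empty output
  expect_equal(nrow(dedupeBestPerSpecies(hits[2:3, ], species)), 2L)
  expect_equal(nrow(dedupeBestPerSpecies(hits[0, ], species)), 0L)
  expect_error(dedupeBestPerSpecies(hits, species[1:2]), "cover")
  # architecture hits combine the two domain E-values
  ah <- data.frame(target_id = c("x1", "x2"),
                   a_evalue = c(1e-3, 1e-9), b_evalue = c(1e-3, 1e-1))
  out2 <- dedupeBestPerSpecies(ah, species)
  expect_equal(out2$target_id, "x2") # 1e-10 < 1e-6
})
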