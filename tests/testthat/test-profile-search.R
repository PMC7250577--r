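# profile construction, windowing, local scoring, E-values, provenance

test_that("profile scores are background log-odds with pseudocounts", {
  aln <- new("SeqAlignment", rows = c(r = "ACD"))
  bg <- rep(1 / 20, 20)
  # near-zero pseudocount: observed residue approaches log2(1/bg), others
  # hit the finite floor
  p <- buildProfile(aln, pseudocountWeight = 1e-9, backgroundFreqs = bg)
  expect_equal(unname(p@matchScores["A", 1]), log2(20), tolerance = 1e-6)
  expect_equal(unname(p@matchScores["C", 2]), log2(20), tolerance = 1e-6)
  expect_equal(unname(p@matchScores["R", 1]), -20) # capped floor
  # monotonicity: the observed residue has the strictly maximal score
  aln2 <- new("SeqAlignment", rows = c(a = "AA", b = "AA", c = "AC"))
  p2 <- buildProfile(aln2, backgroundFreqs = bg)
  expect_equal(unname(which.max(p2@matchScores[, 1])), 1L)
  # row order of the training alignment is irrelevant
  p3 <- buildProfile(new("SeqAlignment", rows = c(c = "AC", a = "AA", b = "AA")),
                     backgroundFreqs = bg)
  expect_equal(unname(p2@matchScores), unname(p3@matchScores))
  # gap-dominated columns are excluded and mapped
  aln4 <- new("SeqAlignment", rows = c(a = "A-C", b = "A-C", c = "A-C",
                                       d = "AQC"))
  p4 <- buildProfile(aln4)
  expect_equal(p4@columnMap, c(1L, 3L))
})

test_that("window counts follow the exact formula", {
  mkAln <- function(L) new("SeqAlignment", rows = c(
    a = paste(rep("A", L), collapse = ""),
    b = paste(rep("C", L), collapse = "")))
  expect_length(windowProfiles(mkAln(60), 60), 1L)
  expect_length(windowProfiles(mkAln(61), 60), 2L)
  expect_error(windowProfiles(mkAln(10), 60), "exceeds")
  # floor((L - w)/step) + 1 for a grid of cases
  for (L in c(60, 73, 100, 141)) {
    for (w in c(10, 35, 60)) {
      for (s in c(1, 3, 7)) {
        wp <- windowProfiles(mkAln(L), w, s)
        expect_length(wp, floor((L - w) / s) + 1)
        if (length(wp) >= 2) expect_equal(wp[[2]]$start - wp[[1]]$start, s)
      }
    }
  }
  # the full-length reference case: 1133 columns, window 60, step 1
  expect_length(windowProfiles(mkAln(1133), 60, 1), 1074L)
})

test_that("local profile scoring finds exact envelopes", {
  seqs <- c(a = "MKLVDAEKQW", b = "MKLVDAEKQW", c = "MKLVDAEKQW")
  p <- buildProfile(new("SeqAlignment", rows = seqs))
  # the training sequence is its own best hit over the full span
  hit <- scoreProfileLocal(p, "MKLVDAEKQW")
  expect_equal(hit$targetStart, 1L)
  expect_equal(hit$targetEnd, 10L)
  # embedded in flanks the envelope still covers exactly the domain
  hit2 <- scoreProfileLocal(p, "GGGGMKLVDAEKQWPPPP")
  expect_equal(hit2$targetStart, 5L)
  expect_equal(hit2$targetEnd, 14L)
  # all-X sequence: nothing scores positive
  hit3 <- scoreProfileLocal(p, "XXXXXXXX")
  expect_equal(hit3$score, 0)
  expect_equal(hit3$targetStart, 0L)
  expect_error(scoreProfileLocal(p, ""), "non-empty")
})

test_that("gapless local scores equal the exhaustive segment oracle", {
  set.seed(31)
  for (rep in 1:15) {
    train <- paste(sample(AA_ALPHABET20, 6, replace = TRUE), collapse = "")
    p <- buildProfile(new("SeqAlignment",
                          rows = c(a = train, b = train)),
                      gapOpen = 1e6, gapExtend = 1e6) # gaps impossible
    s <- paste(sample(AA_ALPHABET20, 8, replace = TRUE), collapse = "")
    got <- scoreProfileLocal(p, s)$score
    expect_equal(got, oracleLocalGaplessScore(p@matchScores, s),
                 tolerance = 1e-9, info = paste(train, s))
  }
})

test_that("E-value calibration behaves like an expected hit count", {
  sc <- generateScenario(scenarioConfig(seed = 10, backgroundCount = 20L))
  p <- buildProfile(sc$seedB)
  expect_error(searchDatabase(p, sc$db), "not calibrated")
  expect_error(calibrateEvalue(p, sc$db, nDecoys = 10), ">= 100")
  p <- calibrateEvalue(p, sc$db, nDecoys = 150, seed = 5)
  # strictly decreasing in score; doubling database size doubles E
  s <- c(5, 10, 20, 40)
  e <- evalueForScore(p, s)
  expect_true(all(diff(e) < 0))
  expect_equal(evalueForScore(p, 12, dbSize = 2 * p@calibration$dbSize),
               2 * evalueForScore(p, 12))
  # on decoys themselves, about one hit with E <= 1 per database scan:
  # count decoy scores whose E-value <= 1, over replicates
  set.seed(99)
  seqs <- sort(dbSequences(sc$db))
  nrep <- 25
  counts <- numeric(nrep)
  dbn <- length(seqs)
  for (r in seq_len(nrep)) {
    sc_ <- vapply(seq_len(dbn), function(i)
      scoreProfileLocal(p, chimeraTrace:::shuffleDecoy(seqs))$score,
      numeric(1))
    counts[r] <- sum(evalueForScore(p, sc_) <= 1)
  }
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / nrep))
})

test_that("database search filters, sorts and respects state", {
  sc <- generateScenario(scenarioConfig(seed = 11, backgroundCount = 10L))
  p <- calibrateEvalue(buildProfile(sc$seedB), sc$db, 120, seed = 2)
  all <- searchDatabase(p, sc$db, Inf)
  expect_setequal(all$target_id, seqIds(sc$db)) # no filtering at E = Inf
  expect_false(is.unsorted(all$e_value))
  empty <- sc$db[character(0)]
  expect_equal(nrow(searchDatabase(p, empty, 1)), 0L)
  # stringent search recovers the bacterial family, no background
  hits <- searchDatabase(p, sc$db, 0.01)
  tx <- taxonomyTable(sc$db)
  bacB <- tx$id[tx$domain_of_life == "Bacteria" & tx$category == "familyB"]
  expect_gte(mean(bacB %in% hits$target_id), 0.9)
  expect_false(any(tx$category[match(hits$target_id, tx$id)] == "background"))
})

test_that("provenance profiles conserve counts and show the chimera signature", {
  sc <- generateScenario(scenarioConfig(seed = 12, backgroundCount = 10L))
  seqs <- dbSequences(sc$db)
  fus <- progressiveMsa(seqs[sc$truth$fusionMemberIds])
  windows <- windowProfiles(fus, windowSize = 60, step = 8)
  windows <- calibrateWindows(windows, sc$db, 120, seed = 3)
  pp <- provenanceProfile(windows, sc$db, 0.01)
  expect_s4_class(pp, "ProvenanceProfile")
  # conservation: recompute one window by hand
  h1 <- searchDatabase(windows[[1]]$profile, sc$db, 0.01)
  expect_equal(sum(pp@counts[1, ]), nrow(h1))
  # domain A windows are eukaryote-dominated, domain B windows bacterial
  firstId <- sc$truth$fusionMemberIds[1]
  spans <- sc$truth$domainSpans[[firstId]]
  lead <- vapply(seq_along(windows), function(i)
    colnames(pp@counts)[which.max(pp@counts[i, ])], character(1))
  starts <- pp@windowStarts
  # map alignment columns to protein coordinates of the first ortholog
  row1 <- strsplit(fus@rows[[firstId]], "")[[1]]
  pos1 <- cumsum(row1 != "-")
  inA <- pos1[pmin(starts + 59, length(pos1))] <= spans$domainA[2]
  inB <- pos1[starts] >= spans$domainB[1]
  expect_true(all(lead[inA] %in% c("Eukaryota_other", "Eukaryota_focal")))
  expect_true(all(lead[inB] == "Bacteria"))
  # empty database gives an all-zero profile
  pp0 <- provenanceProfile(windows, sc$db[character(0)], 0.01)
  expect_true(all(pp0@counts == 0))
})

test_that("null scenarios never show a sustained bacterial-majority signal", {
  # Vertical descent: the bacteria-dominated family is genuinely homologous,
  # so bacterial hits do appear and can even top half of a single window's
  # counts when the archaeal hits happen to drop out. What never occurs
  # without transfer is the stacked-plot signature itself: a sustained run
  # (two or more consecutive scanned windows) in which bacteria hold the
  # majority of hits. (5 seeds)
  for (seed in 501:505) {
    sc <- generateScenario(scenarioConfig(seed = seed,
                                          scenarioKind = "null_vertical",
                                          backgroundCount = 10L))
    seqs <- dbSequences(sc$db)
    fus <- progressiveMsa(seqs[sc$truth$fusionMemberIds])
    windows <- calibrateWindows(windowProfiles(fus, 60, 12), sc$db, 120,
                                splitSeed(seed, 5))
    pp <- provenanceProfile(windows, sc$db, 0.01)
    bacFrac <- pp@counts[, "Bacteria"] / pmax(rowSums(pp@counts), 1)
    dominated <- bacFrac > 0.5
    sustained <- any(dominated[-1] & dominated[-length(dominated)])
    expect_false(sustained,
                 label = paste("no sustained bacterial majority at seed", seed))
  }
})

test_that("profiles serialize to TSV and back", {
  sc <- generateScenario(scenarioConfig(seed = 13, backgroundCount = 0L))
  p <- calibrateEvalue(buildProfile(sc$seedA), sc$db, 120, seed = 4)
  f <- tempfile(fileext = ".tsv")
  writeProfileTsv(p, f)
  q <- readProfileTsv(f)
  expect_equal(q@matchScores, p@matchScores, tolerance = 1e-9)
  expect_equal(q@calibration$location, p@calibration$location,
               tolerance = 1e-9)
  expect_equal(q@columnMap, p@columnMap)
})
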