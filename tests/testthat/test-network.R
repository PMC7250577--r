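# sequence similarity networks

test_that("network construction meets basic contracts", {
  db <- taxSeqDB(c(a = "MKLVDAEKQW", b = "MKLVDAEKQW", c = "WWWWHHHHPPPP"),
                 c("Eukaryota", "Eukaryota", "Bacteria"),
                 c("focal", "familyA", "background"))
  net <- buildNetwork(db, 0.30)
  # identical pair: one edge at identity 1
  expect_equal(nrow(net@edges), 1L)
  expect_equal(net@edges$identity, 1.0)
  expect_setequal(c(net@edges$id1, net@edges$id2), c("a", "b"))
  expect_error(buildNetwork(db[1]), "at least 2")
  # threshold 1.0 on all-distinct sequences: empty edge set
  db2 <- taxSeqDB(c(x = "MKLV", y = "MRLV", z = "AAAA"), "Virus", "background")
  expect_equal(nrow(buildNetwork(db2, 1.0)@edges), 0L)
})

test_that("connected components partition and order correctly", {
  db <- taxSeqDB(c(a = "MKLVDAEKQW", b = "MKLVDAEKQW", c = "WWWWHHHHPPPP"),
                 "Eukaryota", "focal")
  net0 <- buildNetwork(db, 1.0)
  # edgeless graph: all singletons
  netEdgeless <- buildNetwork(taxSeqDB(c(x = "MKLV", y = "AAAA", z = "CCDD"),
                                       "Virus", "background"), 0.99)
  comps <- connectedComponents(netEdgeless)
  expect_length(comps, 3L)
  expect_true(all(lengths(comps) == 1L))
  # two disjoint cliques: exactly two components
  db4 <- taxSeqDB(c(a1 = "MKLVDAEKQW", a2 = "MKLVDAEKQW",
                    b1 = "WWWWHHHHPPPP", b2 = "WWWWHHHHPPPP"),
                  "Eukaryota", "focal")
  comps4 <- connectedComponents(buildNetwork(db4, 0.5))
  expect_length(comps4, 2L)
  expect_setequal(comps4[[1]], c("a1", "a2"))
})

test_that("two simulated families separate into exactly two components", {
  # unrelated families: inter-family identity far below the 0.30 threshold
  mod <- lgModel()
  for (seed in c(4, 9)) {
    trA <- chimeraTrace:::scaleTreeHeight(simulateYuleTree(6, 1, seed), 0.5)
    trB <- chimeraTrace:::scaleTreeHeight(simulateYuleTree(6, 1, seed + 50), 0.5)
    fa <- evolveAlignment(trA, 90, mod, seed + 1)
    fb <- evolveAlignment(trB, 90, mod, seed + 2)
    seqs <- c(stats::setNames(unname(fa@rows), paste0("A_", names(fa@rows))),
              stats::setNames(unname(fb@rows), paste0("B_", names(fb@rows))))
    db <- taxSeqDB(seqs, c(rep("Eukaryota", 6), rep("Bacteria", 6)),
                   c(rep("familyA", 6), rep("familyB", 6)))
    # check the premise: the families are unrelated, so positional
    # identity between them sits at the random-composition baseline
    # (about 6%), far below 15%
    interId <- mean(strsplit(seqs[[1]], "")[[1]] ==
                      strsplit(seqs[[7]], "")[[1]])
    expect_lt(interId, 0.15)
    net <- buildNetwork(db, 0.30)
    comps <- connectedComponents(net)
    nonSingleton <- comps[lengths(comps) > 1]
    expect_length(nonSingleton, 2L)
    # zero inter-family edges
    fams <- substr(net@edges$id1, 1, 1) == substr(net@edges$id2, 1, 1)
    expect_true(all(fams))
    # component count is monotone non-decreasing in the threshold, and
    # components at a higher threshold refine those at a lower one
    comps <- lapply(c(0.2, 0.3, 0.45, 0.6, 0.8, 1.0), function(th)
      connectedComponents(buildNetwork(db, th)))
    expect_true(all(diff(lengths(comps)) >= 0))
    for (k in seq_len(length(comps) - 1)) {
      for (hi in comps[[k + 1]]) {
        containing <- vapply(comps[[k]], function(lo) all(hi %in% lo),
                             logical(1))
        expect_equal(sum(containing), 1L)
      }
    }
  }
})

test_that("networks are invariant to input order", {
  set.seed(3)
  seqs <- stats::setNames(vapply(1:6, function(i)
    paste(sample(AA_ALPHABET20, 30, replace = TRUE), collapse = ""),
    character(1)), paste0("s", 1:6))
  db1 <- taxSeqDB(seqs, "Virus", "background")
  db2 <- db1[rev(names(seqs))]
  n1 <- buildNetwork(db1, 0.1)
  n2 <- buildNetwork(db2, 0.1)
  expect_identical(n1@nodes, n2@nodes)
  expect_identical(n1@edges, n2@edges)
})

test_that("cross-taxon affinity summarizes outgoing edges", {
  db <- taxSeqDB(c(f = "MKLVDAEKQWRR", b1 = "MKLVDAEKQWHH",
                   b2 = "MKLVDAEKYWHH", e1 = "PPPPWWWWCCCC"),
                 c("Eukaryota", "Bacteria", "Bacteria", "Eukaryota"),
                 c("focal", "familyB", "familyB", "familyA"))
  net <- buildNetwork(db, 0.5)
  aff <- crossTaxonAffinity(net, "f")
  expect_false(aff$isolated)
  expect_equal(unname(aff$fractions["Bacteria"]), 1.0)
  expect_equal(sum(aff$fractions), 1.0)
  # isolated focal set
  aff2 <- crossTaxonAffinity(net, "e1")
  expect_true(aff2$isolated)
  expect_error(crossTaxonAffinity(net, "nope"), "network nodes")
})

test_that("network exports are written", {
  db <- taxSeqDB(c(a = "MKLVDAEKQW", b = "MKLVDAEKQW"), "Eukaryota", "focal")
  net <- buildNetwork(db, 0.3)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".graphml")
  writeEdgeListTsv(net, f1)
  writeGraphml(net, f2)
  tsv <- utils::read.delim(f1)
  expect_equal(nrow(tsv), 1L)
  expect_true(any(grepl("graphml", readLines(f2, n = 3))))
})
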