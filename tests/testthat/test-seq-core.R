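# sequence primitives: pairwise alignment, identity, MSA, trimming,
# translation, ORFs, non-redundant databases

test_that("global alignment matches scores that can be verified by hand", {
  b62 <- chimeraTrace:::defaultSubMatrix()
  al <- globalAlign("ACD", "ACD")
  expect_equal(al$score, b62["A", "A"] + b62["C", "C"] + b62["D", "D"])
  expect_equal(al$alignedA, "ACD")
  expect_error(globalAlign("A", ""), "non-empty")
  expect_error(globalAlign("AB1", "ACD"), "illegal residue")
})

test_that("global alignment equals the exhaustive-enumeration oracle", {
  b62 <- chimeraTrace:::defaultSubMatrix()
  al <- globalAlign("HEAGAWGHEE", "PAWHEAE")
  expect_equal(al$score,
               oracleGlobalScore("HEAGAWGHEE", "PAWHEAE", b62, 11, 1))
  # exhaustive small-sequence fixture set over a reduced alphabet
  set.seed(42)
  letters4 <- c("A", "C", "D", "E")
  for (rep in 1:40) {
    a <- paste(sample(letters4, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(letters4, sample(1:6, 1), replace = TRUE), collapse = "")
    go <- sample(c(2, 5, 11), 1); ge <- sample(c(0.5, 1), 1)
    al <- globalAlign(a, b, gapOpen = go, gapExtend = ge)
    expect_equal(al$score, oracleGlobalScore(a, b, b62, go, ge),
                 info = paste(a, b, go, ge))
    # the reported alignment must reproduce the reported score
    expect_equal(nchar(al$alignedA), nchar(al$alignedB))
    expect_identical(gsub("-", "", al$alignedA), a)
    expect_identical(gsub("-", "", al$alignedB), b)
  }
})

test_that("percent identity counts doubly ungapped columns only", {
  expect_equal(percentIdentity("AAAA", "AAAA"), 1.0)
  expect_equal(percentIdentity("AAAT", "AAAA"), 0.75)
  expect_equal(percentIdentity("A--A", "AG-A"), 1.0)
  expect_equal(percentIdentity("-A", "A-"), 0)
  expect_error(percentIdentity("AA", "AAA"), "equal length")
  # symmetry
  set.seed(7)
  for (i in 1:10) {
    a <- paste(sample(c(AA_ALPHABET20, "-"), 12, replace = TRUE), collapse = "")
    b <- paste(sample(c(AA_ALPHABET20, "-"), 12, replace = TRUE), collapse = "")
    expect_equal(percentIdentity(a, b), percentIdentity(b, a))
  }
})

test_that("progressive MSA meets its contracts", {
  expect_error(progressiveMsa(c(x = "ACD")), "at least 2")
  # two sequences reduce to the pairwise aligner
  pw <- globalAlign("HEAGAWGHEE", "PAWHEAE")
  msa2 <- progressiveMsa(c(a = "HEAGAWGHEE", b = "PAWHEAE"))
  expect_identical(unname(msa2@rows[["a"]]), pw$alignedA)
  expect_identical(unname(msa2@rows[["b"]]), pw$alignedB)
  # identical sequences align gap-free
  same <- progressiveMsa(c(a = "MKLV", b = "MKLV", c = "MKLV"))
  expect_equal(nColumns(same), 4L)
  expect_true(all(!grepl("-", same@rows)))
  # round trip: ungapping reproduces inputs; width >= longest input
  set.seed(11)
  seqs <- stats::setNames(vapply(1:5, function(i)
    paste(sample(AA_ALPHABET20, sample(8:15, 1), replace = TRUE),
          collapse = ""), character(1)), paste0("s", 1:5))
  msa <- progressiveMsa(seqs)
  expect_identical(gsub("-", "", msa@rows[names(seqs)]), seqs)
  expect_gte(nColumns(msa), max(nchar(seqs)))
})

test_that("occupancy trimming keeps exactly the dense columns, inclusively", {
  rows <- c(a = "ACDEF", b = "A-DE-", c = "A-D--", d = "A-D--",
            e = "A-DE-", f = "A-DE-", g = "ACDE-", h = "A-DE-",
            i = "A-DE-", j = "A-DE-")
  aln <- new("SeqAlignment", rows = rows)
  # occupancies: 1.0, 0.2, 1.0, 0.7 (exactly at boundary), 0.1
  tr <- trimByOccupancy(aln, 0.70)
  expect_equal(attr(tr, "keptColumns"), c(1L, 3L, 4L))
  expect_error(trimByOccupancy(aln, 0), "in \\(0, 1\\]")
  expect_error(trimByOccupancy(aln, 1.2), "in \\(0, 1\\]")
  # gap-free alignments are unchanged, and trimming is idempotent
  clean <- new("SeqAlignment", rows = c(x = "MKL", y = "MRL"))
  expect_identical(trimByOccupancy(clean)@rows, clean@rows)
  expect_identical(trimByOccupancy(tr, 0.70)@rows, tr@rows)
})

test_that("six-frame translation follows strand and frame conventions", {
  fr <- sixFrameTranslate("ATGAAA")
  expect_identical(unname(fr["F+1"]), "MK")
  expect_identical(unname(sixFrameTranslate("TTTCAT")["F-1"]), "MK")
  expect_error(sixFrameTranslate("AT"), "length >= 3")
  expect_error(sixFrameTranslate("ATGXYZ"), "only A, C, G, T, N")
  # N-containing codons become X; trailing partial codons drop
  expect_identical(unname(sixFrameTranslate("ATGANAC")["F+1"]), "MX")
  # translating the reverse complement swaps the frame triplets
  nt <- "ATGGCCTTAGGCAT"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  f1 <- sixFrameTranslate(nt); f2 <- sixFrameTranslate(rc)
  expect_identical(unname(f1[c("F+1", "F+2", "F+3")]),
                   unname(f2[c("F-1", "F-2", "F-3")]))
  expect_identical(unname(f1[c("F-1", "F-2", "F-3")]),
                   unname(f2[c("F+1", "F+2", "F+3")]))
})

test_that("longest ORF extraction respects tie-breaks and degenerate input", {
  frames <- c("F+1" = "MAAA*", "F+2" = "MA*", "F+3" = "",
              "F-1" = "", "F-2" = "", "F-3" = "")
  res <- longestOrf(frames)
  expect_identical(res$orf, "MAAA")
  expect_identical(res$frame, "F+1")
  # no methionine anywhere: empty result, flagged, not an error
  res2 <- longestOrf(c("F+1" = "AAA", "F+2" = "KK*", "F+3" = "",
                       "F-1" = "", "F-2" = "", "F-3" = ""))
  expect_false(res2$found)
  expect_identical(res2$orf, "")
  # equal lengths: earlier frame wins
  res3 <- longestOrf(c("F+1" = "MAA", "F+2" = "MAA", "F+3" = "",
                       "F-1" = "", "F-2" = "", "F-3" = ""))
  expect_identical(res3$frame, "F+1")
})

test_that("non-redundant database merges identical residue content", {
  db <- taxSeqDB(c(s1 = "MKLV", s2 = "MKLV", s3 = "MRLV"),
                 domain = c("Eukaryota", "Eukaryota", "Bacteria"),
                 category = "familyA")
  nr <- buildNrDatabase(db)
  expect_equal(length(nr), 2L)
  expect_setequal(nr@sourceIds[["s1"]], c("s1", "s2"))
  # conflicting taxonomy collapses to Unknown with a warning
  db2 <- taxSeqDB(c(s1 = "MKLV", s2 = "MKLV"),
                  domain = c("Eukaryota", "Bacteria"), category = "familyA")
  expect_warning(nr2 <- buildNrDatabase(db2), "conflicting")
  expect_identical(nr2@taxonomy$domain_of_life, "Unknown")
  # all-distinct input passes through; idempotence
  db3 <- taxSeqDB(c(a = "MK", b = "MR", c = "ML"), "Virus", "background")
  expect_equal(length(buildNrDatabase(db3)), 3L)
  nr3 <- buildNrDatabase(db3)
  again <- buildNrDatabase(nr3)
  expect_identical(dbSequences(again), dbSequences(nr3))
  expect_identical(again@sourceIds, nr3@sourceIds)
})

test_that("FASTA and taxonomy round-trip through files", {
  db <- taxSeqDB(c(q1 = "MKLVA", q2 = "MMRL"), c("Bacteria", "Eukaryota"),
                 c("familyB", "focal"))
  fa <- tempfile(fileext = ".fasta"); tx <- tempfile(fileext = ".tsv")
  writeTaxSeqDB(db, fa, tx)
  back <- readTaxSeqDB(fa, tx)
  expect_identical(dbSequences(back), dbSequences(db))
  expect_identical(back@taxonomy, db@taxonomy)
  expect_error(readTaxSeqDB("no/such/file.fasta", tx), "no/such/file.fasta")
  aln <- new("SeqAlignment", rows = c(r1 = "MK-L", r2 = "MKQL"))
  af <- tempfile(fileext = ".fasta")
  writeAlignmentFasta(aln, af)
  expect_identical(readAlignmentFasta(af)@rows, aln@rows)
})
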