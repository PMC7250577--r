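#' Configure a simulated two-domain gene scenario
#'
#' The defaults define the package's reference study conditions: a
#' eukaryote-restricted family A (the vertically inherited domain), a
#' bacteria-dominated family B with a few archaeal and eukaryotic homologs,
#' a fusion clade of eukaryote taxa carrying the two-domain gene, and
#' unrelated background proteins. The `chimera` kind plants the fusion
#' gene's B domain inside the bacterial family tree (horizontal transfer);
#' `null_vertical` lets it descend from the eukaryotic family-B ancestor.
#'
#' @param nEukaryoteTaxa,nBacteriaTaxa,nArchaeaTaxa taxon counts.
#' @param nEukFamilyB eukaryote taxa carrying a vertical family-B homolog.
#' @param domainALength,domainBLength domain lengths (residues).
#' @param linkerLengthRange per-lineage linker length range (residues).
#' @param linkerRateMultiplier linker rate relative to the domains.
#' @param fusionCladeSize eukaryote taxa carrying the fusion gene.
#' @param backgroundCount unrelated background proteins.
#' @param scenarioKind "chimera" or "null_vertical".
#' @param treeScale root-to-tip height of the taxon trees (expected
#'   substitutions per site).
#' @param hgtStemLength branch length from the bacterial donor point to the
#'   fusion-clade ancestor (chimera only).
#' @param seed integer seed.
#' @return a [ScenarioConfig-class].
#' @export
scenarioConfig <- function(nEukaryoteTaxa = 10L, nBacteriaTaxa = 8L,
                           nArchaeaTaxa = 3L, nEukFamilyB = 3L,
                           domainALength = 80L, domainBLength = 180L,
                           linkerLengthRange = c(15L, 40L),
                           linkerRateMultiplier = 3,
                           fusionCladeSize = 4L, backgroundCount = 30L,
                           scenarioKind = "chimera", treeScale = 0.7,
                           hgtStemLength = 0.15, seed = 1L) {
  new("ScenarioConfig",
      nEukaryoteTaxa = as.integer(nEukaryoteTaxa),
      nBacteriaTaxa = as.integer(nBacteriaTaxa),
      nArchaeaTaxa = as.integer(nArchaeaTaxa),
      nEukFamilyB = as.integer(nEukFamilyB),
      domainALength = as.integer(domainALength),
      domainBLength = as.integer(domainBLength),
      linkerLengthRange = as.integer(linkerLengthRange),
      linkerRateMultiplier = as.numeric(linkerRateMultiplier),
      fusionCladeSize = as.integer(fusionCladeSize),
      backgroundCount = as.integer(backgroundCount),
      scenarioKind = scenarioKind, treeScale = as.numeric(treeScale),
      hgtStemLength = as.numeric(hgtStemLength), seed = as.integer(seed))
}

# distance of the family-B subfamilies from the family root; chosen so that
# within-reach homologs score far above the stringent E-value threshold
# while cross-domain homologs sit near or below it
FAMB_STEMS <- c(Bacteria = 0.45, Eukaryota = 0.45, Archaea = 0.55)

# build a eukaryote taxon tree in which the fusion clade exists by
# construction: a backbone tree whose designated tip is replaced by the
# fusion subtree
buildEukTree <- function(n, k, height, seed) {
  nb <- n - k + 1L
  if (nb < 2L) stop("nEukaryoteTaxa must exceed fusionCladeSize")
  backbone <- scaleTreeHeight(
    simulateYuleTree(nb, 1, splitSeed(seed, 101L)), height)
  pend <- vapply(seq_len(nb), function(i)
    backbone$edge.length[backbone$edge[, 2] == i], numeric(1))
  attachIdx <- which.max(pend) # deepest pendant branch hosts the clade
  attachLen <- pend[attachIdx]
  labs <- character(nb)
  labs[attachIdx] <- "__ATTACH__"
  labs[-attachIdx] <- sprintf("EUK%02d", seq_len(nb - 1L))
  backbone$tip.label <- labs
  fusion <- scaleTreeHeight(
    simulateYuleTree(k, 1, splitSeed(seed, 102L),
                     tipLabels = sprintf("EUKF%02d", seq_len(k))),
    attachLen / 2)
  txt <- sub("__ATTACH__:[0-9.eE+-]+",
             paste0(sub(";$", "", ape::write.tree(fusion)), ":",
                    format(attachLen / 2, digits = 12)),
             ape::write.tree(backbone))
  ape::read.tree(text = txt)
}

#' Generate a ground-truthed chimera or null scenario
#'
#' Produces the full set of inputs the analysis pipeline consumes: a
#' taxonomically labeled protein database, nucleotide transcripts of the
#' fusion genes, seed alignments for the two domains, and a ground-truth
#' record of everything that was simulated.
#'
#' @param config a [ScenarioConfig-class].
#' @param model substitution model used for all families (default LG with
#'   gamma rate variation).
#' @return a list with elements `db` ([TaxSeqDB-class]), `transcripts`
#'   (named character vector of nucleotide sequences), `seedA`, `seedB`
#'   ([SeqAlignment-class] seed alignments of the two domains), and `truth`
#'   (list: fusionMemberIds, donorTaxonDomain, trueTrees, taxonomy,
#'   speciesOf, domainSpans, linker details, trees).
#' @export
generateScenario <- function(config, model = lgModel()) {
  validObject(config)
  seed <- config@seed
  kind <- config@scenarioKind
  LA <- config@domainALength
  LB <- config@domainBLength
  eig <- modelEigen(model)

  # --- taxon trees ---------------------------------------------------------
  eukTree <- buildEukTree(config@nEukaryoteTaxa, config@fusionCladeSize,
                          config@treeScale, seed)
  fusionTaxa <- sort(grep("^EUKF", eukTree$tip.label, value = TRUE))
  bacTree <- scaleTreeHeight(
    simulateYuleTree(config@nBacteriaTaxa, 1, splitSeed(seed, 2L),
                     tipLabels = sprintf("BAC%02d", seq_len(config@nBacteriaTaxa))),
    config@treeScale)
  arcTree <- if (config@nArchaeaTaxa >= 2L)
    scaleTreeHeight(
      simulateYuleTree(config@nArchaeaTaxa, 1, splitSeed(seed, 3L),
                       tipLabels = sprintf("ARC%02d", seq_len(config@nArchaeaTaxa))),
      config@treeScale / 2) else NULL

  seqs <- character(0)
  dom <- character(0)
  cat_ <- character(0)

  addSeq <- function(id, residues, domain, category) {
    seqs[id] <<- residues
    dom[id] <<- domain
    cat_[id] <<- category
  }

  # --- family A: eukaryote-restricted domain -------------------------------
  famA <- evolveAlignment(eukTree, LA, model, splitSeed(seed, 4L),
                          returnAncestors = TRUE)
  for (tx in eukTree$tip.label)
    addSeq(paste0(tx, "_famA"), famA@rows[[tx]], "Eukaryota", "familyA")

  # fusion domain A: a paralog duplicated at the fusion-clade ancestor and
  # re-evolved along the fusion subtree (still inside the eukaryote family)
  fusionMrca <- ape::getMRCA(eukTree, fusionTaxa)
  ancA <- attr(famA, "ancestralCodes")[fusionMrca - length(eukTree$tip.label), ]
  fusionSub <- ape::extract.clade(eukTree, fusionMrca)
  dupStemSeed <- splitSeed(seed, 5L)
  ratesA <- attr(famA, "siteRates")
  ancAdup <- evolveBranch(ancA, 0.10, eig, ratesA, dupStemSeed)
  fusA <- evolveAlignment(fusionSub, LA, model, splitSeed(seed, 6L),
                          rootCodes = ancAdup, siteRates = ratesA)

  # --- family B: bacteria-dominated domain ---------------------------------
  ratesB <- eig$rates[withr_seed(splitSeed(seed, 7L), function()
    sample.int(length(eig$rates), LB, replace = TRUE))]
  rootB <- withr_seed(splitSeed(seed, 8L), function()
    sample.int(20L, LB, replace = TRUE, prob = eig$pi))

  bacRoot <- evolveBranch(rootB, FAMB_STEMS[["Bacteria"]], eig, ratesB,
                          splitSeed(seed, 9L))
  famBbac <- evolveAlignment(bacTree, LB, model, splitSeed(seed, 10L),
                             rootCodes = bacRoot, siteRates = ratesB,
                             returnAncestors = TRUE)
  for (tx in bacTree$tip.label)
    addSeq(paste0(tx, "_famB"), famBbac@rows[[tx]], "Bacteria", "familyB")

  if (!is.null(arcTree)) {
    arcRoot <- evolveBranch(rootB, FAMB_STEMS[["Archaea"]], eig, ratesB,
                            splitSeed(seed, 11L))
    famBarc <- evolveAlignment(arcTree, LB, model, splitSeed(seed, 12L),
                               rootCodes = arcRoot, siteRates = ratesB)
    for (tx in arcTree$tip.label)
      addSeq(paste0(tx, "_famB"), famBarc@rows[[tx]], "Archaea", "familyB")
  }

  # eukaryotic family-B carriers (and, in the null scenario, the fusion
  # lineages) descend vertically from the eukaryotic family-B ancestor
  nonFusion <- setdiff(eukTree$tip.label, fusionTaxa)
  carriers <- sort(withr_seed(splitSeed(seed, 13L), function()
    sample(nonFusion, min(config@nEukFamilyB, length(nonFusion)))))
  eukRootB <- evolveBranch(rootB, FAMB_STEMS[["Eukaryota"]], eig, ratesB,
                           splitSeed(seed, 14L))
  eukBtaxa <- if (kind == "null_vertical") sort(c(carriers, fusionTaxa))
    else carriers
  eukBseqs <- NULL
  if (length(eukBtaxa) >= 2L) {
    eukBtree <- ape::keep.tip(eukTree, eukBtaxa)
    eukB <- evolveAlignment(eukBtree, LB, model, splitSeed(seed, 15L),
                            rootCodes = eukRootB, siteRates = ratesB)
    eukBseqs <- eukB@rows
  } else if (length(eukBtaxa) == 1L) {
    depth <- max(ape::node.depth.edgelength(eukTree))
    one <- evolveBranch(eukRootB, depth, eig, ratesB, splitSeed(seed, 16L))
    eukBseqs <- stats::setNames(aaString(one), eukBtaxa)
  }
  for (tx in carriers)
    addSeq(paste0(tx, "_famB"), eukBseqs[[tx]], "Eukaryota", "familyB")

  # --- fusion domain B -----------------------------------------------------
  donorEdge <- NA_integer_
  if (kind == "chimera") {
    # donor branches must lie strictly inside the bacterial crown group:
    # a branch incident to the root carries almost no nested signal (the
    # attachment differs from a sister-group placement by a fraction of a
    # single branch), which is not the transfer this scenario emulates
    nb <- length(bacTree$tip.label)
    rootNode <- nb + 1L
    internalEdges <- which(bacTree$edge[, 2] > nb &
                             bacTree$edge[, 1] != rootNode)
    if (!length(internalEdges))
      internalEdges <- which(bacTree$edge[, 2] > nb)
    donorEdge <- internalEdges[withr_seed(splitSeed(seed, 17L), function()
      sample.int(length(internalEdges), 1L))]
    donorParent <- bacTree$edge[donorEdge, 1]
    donorLen <- bacTree$edge.length[donorEdge]
    ancRow <- donorParent - length(bacTree$tip.label)
    donorAnc <- attr(famBbac, "ancestralCodes")[ancRow, ]
    donorMid <- evolveBranch(donorAnc, donorLen / 2, eig, ratesB,
                             splitSeed(seed, 18L))
    fusBroot <- evolveBranch(donorMid, config@hgtStemLength, eig, ratesB,
                             splitSeed(seed, 19L))
    fusB <- evolveAlignment(fusionSub, LB, model, splitSeed(seed, 20L),
                            rootCodes = fusBroot, siteRates = ratesB)
    fusBseqs <- fusB@rows
  } else {
    fusBseqs <- eukBseqs[fusionTaxa]
  }

  # --- linkers: fast-evolving, per-lineage length, indels confined here ----
  linkLmax <- config@linkerLengthRange[2]
  linkRates <- eig$rates[withr_seed(splitSeed(seed, 21L), function()
    sample.int(length(eig$rates), linkLmax, replace = TRUE))]
  linkRoot <- withr_seed(splitSeed(seed, 22L), function()
    sample.int(20L, linkLmax, replace = TRUE, prob = eig$pi))
  linkAln <- evolveAlignment(fusionSub, linkLmax, model, splitSeed(seed, 23L),
                             rateMultiplier = config@linkerRateMultiplier,
                             rootCodes = linkRoot, siteRates = linkRates)
  set.seed(splitSeed(seed, 24L))
  linkLens <- sample(seq(config@linkerLengthRange[1],
                         config@linkerLengthRange[2]),
                     length(fusionTaxa), replace = TRUE)
  names(linkLens) <- fusionTaxa
  linkers <- vapply(fusionTaxa, function(tx) {
    full <- strsplit(linkAln@rows[[tx]], "")[[1]]
    keep <- sort(sample.int(linkLmax, linkLens[[tx]]))
    paste(full[keep], collapse = "")
  }, character(1))

  # --- assemble fusion proteins -------------------------------------------
  fusionIds <- paste0(fusionTaxa, "_fusion")
  domainSpans <- list()
  for (i in seq_along(fusionTaxa)) {
    tx <- fusionTaxa[i]
    dA <- fusA@rows[[tx]]; lk <- linkers[[tx]]; dB <- fusBseqs[[tx]]
    protein <- paste0("M", dA, lk, dB)
    addSeq(fusionIds[i], protein, "Eukaryota", "focal")
    aStart <- 2L; aEnd <- 1L + LA
    lStart <- aEnd + 1L; lEnd <- aEnd + nchar(lk)
    bStart <- lEnd + 1L; bEnd <- lEnd + LB
    domainSpans[[fusionIds[i]]] <- list(
      domainA = c(aStart, aEnd),
      linker = if (nchar(lk)) c(lStart, lEnd) else integer(0),
      domainB = c(bStart, bEnd))
  }

  # --- background proteins -------------------------------------------------
  set.seed(splitSeed(seed, 25L))
  if (config@backgroundCount > 0) {
    bgLens <- sample(80:250, config@backgroundCount, replace = TRUE)
    bgDom <- sample(c("Bacteria", "Eukaryota", "Archaea", "Virus"),
                    config@backgroundCount, replace = TRUE,
                    prob = c(0.4, 0.4, 0.1, 0.1))
    for (i in seq_len(config@backgroundCount)) {
      res <- aaString(sample.int(20L, bgLens[i], replace = TRUE, prob = eig$pi))
      addSeq(sprintf("BG%03d", i), res, bgDom[i], "background")
    }
  }

  db <- taxSeqDB(seqs, dom, cat_)

  # --- transcripts of the fusion genes -------------------------------------
  transcripts <- character(0)
  for (i in seq_along(fusionIds)) {
    transcripts[paste0(fusionIds[i], "_tx")] <-
      buildTranscript(seqs[[fusionIds[i]]], splitSeed(seed, 300L + i))
  }

  # --- seed alignments: the three first-known fusion orthologs -------------
  seedTaxa <- fusionTaxa[seq_len(min(3L, length(fusionTaxa)))]
  seedA <- new("SeqAlignment",
               rows = stats::setNames(vapply(seedTaxa, function(tx)
                 fusA@rows[[tx]], character(1)),
                 paste0(seedTaxa, "_fusion")))
  seedB <- new("SeqAlignment",
               rows = stats::setNames(vapply(seedTaxa, function(tx)
                 fusBseqs[[tx]], character(1)),
                 paste0(seedTaxa, "_fusion")))

  # --- ground truth ---------------------------------------------------------
  ids <- names(seqs)
  speciesOf <- sub("_(famA|famB|fusion)$", "", ids)
  names(speciesOf) <- ids
  trueB <- buildTrueFamilyBTree(bacTree, arcTree, eukTree, carriers,
                                fusionTaxa, kind, donorEdge,
                                config@hgtStemLength)
  truth <- list(
    fusionMemberIds = fusionIds,
    donorTaxonDomain = if (kind == "chimera") "Bacteria" else "Eukaryota",
    trueTrees = list(familyA = eukTree, familyB = trueB),
    taxonomy = db@taxonomy,
    speciesOf = speciesOf,
    domainSpans = domainSpans,
    fusionTaxa = fusionTaxa,
    carriers = carriers,
    linker = list(root = aaString(linkRoot), fullRows = linkAln@rows,
                  rootCodesA = ancAdup, famARoot = famA,
                  fusionDomainA = fusA),
    scenarioKind = kind, seed = seed)
  list(db = db, transcripts = transcripts, seedA = seedA, seedB = seedB,
       truth = truth, eukTree = eukTree, bacTree = bacTree,
       arcTree = arcTree, config = config)
}

# run `fn` under a temporary seed
withr_seed <- function(seed, fn) {
  set.seed(seed)
  fn()
}

# the true gene tree of family B, for ground-truth comparisons
buildTrueFamilyBTree <- function(bacTree, arcTree, eukTree, carriers,
                                 fusionTaxa, kind, donorEdge, hgtStem) {
  lab <- function(tr, suffix) {
    tr$tip.label <- paste0(tr$tip.label, suffix)
    tr
  }
  bac <- lab(bacTree, "_famB")
  eukTaxa <- if (kind == "null_vertical") c(carriers, fusionTaxa) else carriers
  if (kind == "chimera" && !is.na(donorEdge)) {
    fus <- ape::extract.clade(eukTree, ape::getMRCA(eukTree, fusionTaxa))
    fus$tip.label <- paste0(fus$tip.label, "_fusion")
    fus$root.edge <- hgtStem + bacTree$edge.length[donorEdge] / 2
    bac <- ape::bind.tree(bac, fus, where = bacTree$edge[donorEdge, 2],
                          position = bacTree$edge.length[donorEdge] / 2)
  }
  parts <- paste0(sub(";$", "", ape::write.tree(bac)), ":",
                  FAMB_STEMS[["Bacteria"]])
  if (length(eukTaxa) >= 2L) {
    euk <- ape::keep.tip(eukTree, eukTaxa)
    euk$tip.label <- paste0(euk$tip.label,
                            ifelse(euk$tip.label %in% fusionTaxa &
                                     kind == "null_vertical",
                                   "_fusion", "_famB"))
    parts <- c(parts, paste0(sub(";$", "", ape::write.tree(euk)), ":",
                             FAMB_STEMS[["Eukaryota"]]))
  } else if (length(eukTaxa) == 1L) {
    parts <- c(parts, paste0(eukTaxa, "_famB:", FAMB_STEMS[["Eukaryota"]]))
  }
  if (!is.null(arcTree)) {
    arc <- lab(arcTree, "_famB")
    parts <- c(parts, paste0(sub(";$", "", ape::write.tree(arc)), ":",
                             FAMB_STEMS[["Archaea"]]))
  }
  ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
}

# reverse-translate a protein and embed it in UTRs on a random strand; the
# longest open reading frame of the result is exactly the input protein
buildTranscript <- function(protein, seed) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  codonsOf <- split(names(gc), gc)
  stops <- codonsOf[["*"]]
  aas <- strsplit(protein, "")[[1]]
  for (attempt in 1:25) {
    cds <- vapply(aas, function(a) {
      cc <- codonsOf[[a]]
      cc[sample.int(length(cc), 1L)]
    }, character(1))
    cds[1] <- "ATG"
    cds <- c(cds, stops[sample.int(length(stops), 1L)])
    utr5len <- 3L * sample(8:25, 1L)
    utr5 <- paste(sample(c("A", "C", "G", "T"), utr5len - 3L, replace = TRUE),
                  collapse = "")
    # in-frame stop immediately upstream keeps the ORF call exact
    utr5 <- paste0(utr5, "TAA")
    utr3 <- paste(sample(c("A", "C", "G", "T"), sample(20:60, 1L),
                         replace = TRUE), collapse = "")
    tx <- paste0(utr5, paste(cds, collapse = ""), utr3)
    if (sample(c(TRUE, FALSE), 1L))
      tx <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tx)))
    orf <- longestOrf(sixFrameTranslate(tx))
    if (identical(orf$orf, protein)) return(tx)
  }
  stop("failed to build a transcript with an exact ORF round-trip")
}
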