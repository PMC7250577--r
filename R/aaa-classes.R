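#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib chimeraTrace, .registration = TRUE
NULL

#' The 20 amino-acid letters in the canonical order used throughout
#'
#' Matches the row order of the BLOSUM62 matrix shipped with Biostrings and
#' of the LG rate matrix, so residue codes are interchangeable between the
#' alignment and likelihood layers.
#' @export
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

DOMAINS_OF_LIFE <- c("Eukaryota", "Bacteria", "Archaea", "Virus", "Unknown")

# ---------------------------------------------------------------------------
# SubstitutionModel

#' Reversible amino-acid substitution model
#'
#' Holds symmetric exchangeabilities, equilibrium frequencies and the
#' discrete-gamma rate heterogeneity settings. The rate matrix built from it
#' is always rescaled so that one unit of branch length equals one expected
#' substitution per site, and the discrete-gamma category rates have mean 1.
#'
#' @slot exchangeabilities symmetric 20x20 matrix of rate multipliers
#'   (diagonal ignored).
#' @slot equilibriumFreqs length-20 vector summing to 1.
#' @slot gammaShape positive shape of the gamma rate distribution.
#' @slot nRateCategories number of discrete gamma categories (1 disables
#'   rate heterogeneity).
#' @slot name short label used in printouts.
#' @export
setClass("SubstitutionModel",
  representation(exchangeabilities = "matrix", equilibriumFreqs = "numeric",
                 gammaShape = "numeric", nRateCategories = "integer",
                 name = "character"),
  validity = function(object) {
    ex <- object@exchangeabilities
    fr <- object@equilibriumFreqs
    if (!all(dim(ex) == c(20L, 20L))) return("exchangeabilities must be 20x20")
    if (max(abs(ex - t(ex))) > 1e-10) return("exchangeabilities must be symmetric")
    if (any(ex[upper.tri(ex)] < 0)) return("exchangeabilities must be non-negative")
    if (length(fr) != 20L) return("equilibriumFreqs must have length 20")
    if (any(fr <= 0)) return("equilibriumFreqs must be positive")
    if (abs(sum(fr) - 1) > 1e-12) return("equilibriumFreqs must sum to 1")
    if (length(object@gammaShape) != 1L || object@gammaShape <= 0)
      return("gammaShape must be a positive scalar")
    if (object@nRateCategories < 1L) return("nRateCategories must be >= 1")
    TRUE
  })

setMethod("show", "SubstitutionModel", function(object) {
  cat("SubstitutionModel:", object@name, "\n")
  cat("  gamma shape", object@gammaShape, "with", object@nRateCategories,
      "rate categories\n")
})

# ---------------------------------------------------------------------------
# TaxSeqDB

#' Taxonomically labeled protein sequence database
#'
#' Wraps a [Biostrings::AAStringSet] together with a taxonomy table
#' (one row per record: `id`, `domain_of_life`, `category`) and the
#' provenance of merged records.
#'
#' @slot sequences an `AAStringSet`, one record per unique id.
#' @slot taxonomy data.frame with columns id, domain_of_life, category.
#' @slot sourceIds named list mapping each id to the original ids merged
#'   into it.
#' @export
setClass("TaxSeqDB",
  representation(sequences = "ANY", taxonomy = "data.frame",
                 sourceIds = "list"),
  validity = function(object) {
    ids <- names(object@sequences)
    if (is.null(ids) || anyDuplicated(ids)) return("sequence ids must be unique")
    if (any(Biostrings::width(object@sequences) == 0))
      return("sequences must be non-empty")
    tx <- object@taxonomy
    need <- c("id", "domain_of_life", "category")
    if (!all(need %in% names(tx))) return("taxonomy must have id, domain_of_life, category")
    if (!setequal(tx$id, ids) || nrow(tx) != length(ids))
      return("taxonomy must cover every record exactly once")
    if (!all(tx$domain_of_life %in% DOMAINS_OF_LIFE))
      return(paste("domain_of_life must be one of:",
                   paste(DOMAINS_OF_LIFE, collapse = ", ")))
    TRUE
  })

setMethod("show", "TaxSeqDB", function(object) {
  tab <- table(object@taxonomy$domain_of_life)
  cat("TaxSeqDB with", length(object@sequences), "records (",
      paste(names(tab), tab, collapse = ", "), ")\n")
})

setMethod("length", "TaxSeqDB", function(x) length(x@sequences))

setMethod("[", "TaxSeqDB", function(x, i, j, ..., drop = TRUE) {
  ids <- if (is.character(i)) i else names(x@sequences)[i]
  new("TaxSeqDB", sequences = x@sequences[ids],
      taxonomy = x@taxonomy[match(ids, x@taxonomy$id), , drop = FALSE],
      sourceIds = x@sourceIds[ids])
})

# ---------------------------------------------------------------------------
# SeqAlignment

#' Protein multiple sequence alignment
#'
#' Rows are gapped sequences of equal width over the 20 amino-acid letters,
#' `X` and the gap character `-`.
#'
#' @slot rows named character vector of gapped sequences.
#' @export
setClass("SeqAlignment",
  representation(rows = "character"),
  validity = function(object) {
    if (length(object@rows) == 0) return("alignment must have at least one row")
    if (is.null(names(object@rows)) || anyDuplicated(names(object@rows)))
      return("row ids must be unique")
    wid <- unique(nchar(object@rows))
    if (length(wid) != 1) return("all rows must have equal width")
    ok <- grepl(paste0("^[", paste(AA_ALPHABET20, collapse = ""), "X-]*$"),
                object@rows)
    if (!all(ok)) return("rows may contain only amino-acid letters, X and -")
    TRUE
  })

setMethod("show", "SeqAlignment", function(object) {
  cat("SeqAlignment:", length(object@rows), "rows x",
      nchar(object@rows[[1]]), "columns\n")
})

# ---------------------------------------------------------------------------
# ProfileModel

#' Position-specific log-odds scoring profile
#'
#' A lightweight substitute for a profile HMM: per-column match scores in
#' bits plus affine gap penalties. Columns of the source alignment with
#' occupancy below 0.5 are excluded from the model; `columnMap` records the
#' source column of each retained profile column. Search E-values require a
#' calibration (Gumbel location/scale plus the database size used), attached
#' by [calibrateEvalue()].
#'
#' @slot matchScores 20 x n_columns matrix of log2-odds scores (bits).
#' @slot backgroundFreqs length-20 background distribution.
#' @slot gapOpen,gapExtend positive affine gap penalties in bits.
#' @slot pseudocountWeight weight of the background pseudocount.
#' @slot columnMap integer vector mapping profile columns to source columns.
#' @slot calibration empty list, or list(location, scale, dbSize).
#' @export
setClass("ProfileModel",
  representation(matchScores = "matrix", backgroundFreqs = "numeric",
                 gapOpen = "numeric", gapExtend = "numeric",
                 pseudocountWeight = "numeric", columnMap = "integer",
                 calibration = "list"),
  validity = function(object) {
    if (nrow(object@matchScores) != 20L) return("matchScores must have 20 rows")
    if (ncol(object@matchScores) < 1L) return("profile must have >= 1 column")
    if (!all(is.finite(object@matchScores))) return("matchScores must be finite")
    if (abs(sum(object@backgroundFreqs) - 1) > 1e-9)
      return("backgroundFreqs must sum to 1")
    if (object@gapOpen <= 0 || object@gapExtend <= 0)
      return("gap penalties must be positive")
    if (object@pseudocountWeight <= 0) return("pseudocountWeight must be positive")
    if (length(object@columnMap) != ncol(object@matchScores))
      return("columnMap must match the number of profile columns")
    TRUE
  })

setMethod("show", "ProfileModel", function(object) {
  cat("ProfileModel with", ncol(object@matchScores), "match columns;",
      if (length(object@calibration)) "calibrated" else "uncalibrated", "\n")
})

# ---------------------------------------------------------------------------
# ProvenanceProfile

#' Sliding-window taxonomic provenance profile
#'
#' For each 60-column (by default) window of a query alignment, the number
#' of database hits per taxonomic category: the data behind a stacked
#' provenance plot.
#'
#' @slot windowStarts 1-based alignment-column index of each window.
#' @slot windowSize window width in alignment columns.
#' @slot counts matrix of non-negative counts, one row per window, one
#'   column per category.
#' @export
setClass("ProvenanceProfile",
  representation(windowStarts = "integer", windowSize = "integer",
                 counts = "matrix"),
  validity = function(object) {
    if (nrow(object@counts) != length(object@windowStarts))
      return("one count row per window required")
    if (any(object@counts < 0)) return("counts must be non-negative")
    if (is.null(colnames(object@counts))) return("count columns must be named")
    TRUE
  })

setMethod("show", "ProvenanceProfile", function(object) {
  cat("ProvenanceProfile:", length(object@windowStarts), "windows of",
      object@windowSize, "columns;", paste(colnames(object@counts), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# SimilarityNetwork

#' Sequence similarity network
#'
#' Undirected graph whose nodes are sequences and whose edges connect pairs
#' with global percent identity at or above a threshold.
#'
#' @slot nodes data.frame with columns id, domain_of_life, category.
#' @slot edges data.frame with columns id1, id2, identity, score
#'   (id1 < id2, no duplicates, no self loops).
#' @slot threshold identity threshold in `[0, 1]`.
#' @export
setClass("SimilarityNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 threshold = "numeric"),
  validity = function(object) {
    ed <- object@edges
    if (nrow(ed)) {
      if (any(ed$id1 == ed$id2)) return("self-loops are not allowed")
      if (any(ed$id1 > ed$id2)) return("edges must be stored with id1 < id2")
      if (anyDuplicated(paste(ed$id1, ed$id2))) return("duplicate edges")
      if (!all(c(ed$id1, ed$id2) %in% object@nodes$id))
        return("edge endpoints must be nodes")
      if (any(ed$identity < object@threshold - 1e-12))
        return("all edges must meet the identity threshold")
    }
    TRUE
  })

setMethod("show", "SimilarityNetwork", function(object) {
  cat("SimilarityNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges at identity >=", object@threshold, "\n")
})

# ---------------------------------------------------------------------------
# SOWHResult

#' Result of a SOWH constrained-topology test
#'
#' @slot observedDelta observed log-likelihood difference between the
#'   unconstrained and constrained maximum-likelihood trees (>= 0).
#' @slot nullDeltas the same statistic on each parametric-bootstrap
#'   replicate simulated under the constrained tree.
#' @slot pValue (1 + #\{null >= observed\}) / (1 + n_sims).
#' @slot nSims number of simulations.
#' @slot convergedSims number of simulations whose tree searches converged.
#' @export
setClass("SOWHResult",
  representation(observedDelta = "numeric", nullDeltas = "numeric",
                 pValue = "numeric", nSims = "integer",
                 convergedSims = "integer"),
  validity = function(object) {
    if (length(object@nullDeltas) != object@nSims)
      return("nullDeltas must have length nSims")
    expect <- (1 + sum(object@nullDeltas >= object@observedDelta)) /
      (1 + object@nSims)
    if (abs(object@pValue - expect) > 1e-12)
      return("pValue must follow the (1+k)/(1+n) rule")
    if (object@observedDelta < 0) return("observedDelta must be >= 0")
    TRUE
  })

setMethod("show", "SOWHResult", function(object) {
  cat(sprintf("SOWH test: observed delta lnL = %.4f, p = %.4g (%d sims)\n",
              object@observedDelta, object@pValue, object@nSims))
})

# ---------------------------------------------------------------------------
# DiscoveryState

#' State of the iterative two-domain ortholog discovery
#'
#' @slot round number of completed search rounds.
#' @slot acceptedIds ids accepted so far (monotone across rounds).
#' @slot alignmentA,alignmentB growing domain alignments.
#' @slot profileA,profileB profiles built from the final alignments.
#' @slot converged TRUE if the accepted set reached a fixed point.
#' @slot log per-round data.frame (round, n_accepted, n_new).
#' @export
setClass("DiscoveryState",
  representation(round = "integer", acceptedIds = "character",
                 alignmentA = "SeqAlignment", alignmentB = "SeqAlignment",
                 profileA = "ProfileModel", profileB = "ProfileModel",
                 converged = "logical", log = "data.frame"))

setMethod("show", "DiscoveryState", function(object) {
  cat("DiscoveryState:", length(object@acceptedIds), "accepted ids after",
      object@round, "rounds;",
      if (object@converged) "converged" else "NOT converged", "\n")
})

# ---------------------------------------------------------------------------
# ScenarioConfig

#' Configuration of a simulated chimera or null scenario
#'
#' @slot nEukaryoteTaxa,nBacteriaTaxa,nArchaeaTaxa taxon counts per domain
#'   of life.
#' @slot nEukFamilyB number of eukaryote taxa carrying a vertically
#'   inherited member of family B (the analog of the handful of eukaryotic
#'   hydrolase homologs in real searches).
#' @slot domainALength,domainBLength domain lengths in residues.
#' @slot linkerLengthRange two integers, the per-lineage linker length range.
#' @slot linkerRateMultiplier relative evolutionary rate of the linker.
#' @slot fusionCladeSize number of eukaryote taxa carrying the fusion gene.
#' @slot backgroundCount number of unrelated background proteins.
#' @slot scenarioKind "chimera" or "null_vertical".
#' @slot treeScale root-to-tip height (expected substitutions per site) that
#'   family trees are scaled to.
#' @slot hgtStemLength branch length between the donor point and the fusion
#'   clade ancestor.
#' @slot seed integer seed.
#' @export
setClass("ScenarioConfig",
  representation(nEukaryoteTaxa = "integer", nBacteriaTaxa = "integer",
                 nArchaeaTaxa = "integer", nEukFamilyB = "integer",
                 domainALength = "integer", domainBLength = "integer",
                 linkerLengthRange = "integer", linkerRateMultiplier = "numeric",
                 fusionCladeSize = "integer", backgroundCount = "integer",
                 scenarioKind = "character", treeScale = "numeric",
                 hgtStemLength = "numeric", seed = "integer"),
  validity = function(object) {
    counts <- c(object@nEukaryoteTaxa, object@nBacteriaTaxa,
                object@nArchaeaTaxa, object@nEukFamilyB,
                object@backgroundCount, object@fusionCladeSize)
    if (any(counts < 0)) return("all counts must be >= 0")
    if (!object@scenarioKind %in% c("chimera", "null_vertical"))
      return("scenarioKind must be 'chimera' or 'null_vertical'")
    if (object@scenarioKind == "chimera" &&
        (object@nBacteriaTaxa < 2L || object@fusionCladeSize < 3L))
      return("chimera scenario requires nBacteriaTaxa >= 2 and fusionCladeSize >= 3")
    if (object@fusionCladeSize > object@nEukaryoteTaxa)
      return("fusionCladeSize cannot exceed nEukaryoteTaxa")
    if (length(object@linkerLengthRange) != 2L ||
        any(object@linkerLengthRange < 1L) ||
        diff(object@linkerLengthRange) < 0)
      return("linkerLengthRange must be two increasing positive integers")
    if (object@linkerRateMultiplier <= 0)
      return("linkerRateMultiplier must be positive")
    TRUE
  })

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig:", object@scenarioKind, "scenario,",
      object@nEukaryoteTaxa, "eukaryotes /", object@nBacteriaTaxa,
      "bacteria /", object@nArchaeaTaxa, "archaea, fusion clade of",
      object@fusionCladeSize, "(seed", paste0(object@seed, ")"), "\n")
})

# ---------------------------------------------------------------------------
# ChimeraReport

#' End product of the pipeline: per-domain origin calls with evidence
#'
#' @slot domains named list (one entry per analyzed domain) holding the
#'   affinity call, sister-group taxa, network affinity summary, SOWH result
#'   and pointers to intermediate artifacts.
#' @slot metadata list with the seed, config hash and package version.
#' @export
setClass("ChimeraReport",
  representation(domains = "list", metadata = "list"),
  validity = function(object) {
    for (d in object@domains) {
      if (is.null(d$affinity_call)) return("every domain needs an affinity_call")
      if (identical(d$affinity_call$type, "nested_in") && is.null(d$sowh))
        return("a nested_in call requires an attached SOWH result")
    }
    TRUE
  })

setMethod("show", "ChimeraReport", function(object) {
  cat("ChimeraReport (seed", object@metadata$seed, ")\n")
  for (nm in names(object@domains)) {
    d <- object@domains[[nm]]
    call <- d$affinity_call
    lab <- if (call$type == "unresolved") "unresolved"
      else paste0(call$type, " ", call$taxon)
    p <- if (!is.null(d$sowh)) sprintf(" (SOWH p = %.4g)", d$sowh$p_value) else ""
    cat(" ", nm, ":", lab, p, "\n")
  }
})

# ---------------------------------------------------------------------------
# shared generics

#' Number of columns of an alignment or profile
#' @param x a SeqAlignment or ProfileModel.
#' @return integer column count.
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @rdname nColumns
setMethod("nColumns", "SeqAlignment", function(x) nchar(x@rows[[1]]))

#' @rdname nColumns
setMethod("nColumns", "ProfileModel", function(x) ncol(x@matchScores))
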