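# per-domain sequence similarity networks

#' Build a sequence similarity network
#'
#' All-vs-all global alignment; an undirected edge connects two sequences
#' when their percent identity (over doubly ungapped columns) reaches the
#' threshold. The conventional threshold for domain-level family structure
#' is 30% identity. Node and edge order are canonical (sorted ids), so the
#' network is invariant to input order.
#'
#' @param db a [TaxSeqDB-class] with >= 2 records.
#' @param identityThreshold edge threshold in `[0, 1]` (default 0.30).
#' @param substitutionMatrix,gapOpen,gapExtend alignment parameters, see
#'   [globalAlign()].
#' @param localIdentity use the best local alignment instead of the global
#'   one when computing identity.
#' @return a [SimilarityNetwork-class].
#' @export
buildNetwork <- function(db, identityThreshold = 0.30,
                         substitutionMatrix = defaultSubMatrix(),
                         gapOpen = 11, gapExtend = 1,
                         localIdentity = FALSE) {
  seqs <- dbSequences(db)
  if (length(seqs) < 2L) stop("a network needs at least 2 sequences")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  ids <- sort(names(seqs))
  tx <- db@taxonomy
  nodes <- data.frame(id = ids,
                      domain_of_life = tx$domain_of_life[match(ids, tx$id)],
                      category = tx$category[match(ids, tx$id)],
                      stringsAsFactors = FALSE)
  edges <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      a <- seqs[[ids[i]]]; b <- seqs[[ids[j]]]
      if (localIdentity) {
        S <- pairScoreMatrix(a, b, substitutionMatrix)
        loc <- cpp_affine_local(S, gapOpen, gapExtend)
        if (loc$score <= 0) next
        al <- globalAlign(substr(a, loc$row_start, loc$row_end),
                          substr(b, loc$col_start, loc$col_end),
                          substitutionMatrix, gapOpen, gapExtend)
        score <- loc$score
      } else {
        al <- globalAlign(a, b, substitutionMatrix, gapOpen, gapExtend)
        score <- al$score
      }
      pid <- percentIdentity(al$alignedA, al$alignedB)
      # the identity is computed over doubly ungapped columns, which can be
      # spuriously high for unrelated sequences aligned mostly through gaps;
      # requiring a positive alignment score screens those out (thresholding
      # on score is also how similarity-network tools operate)
      if (pid >= identityThreshold && score > 0) {
        edges[[length(edges) + 1L]] <-
          data.frame(id1 = ids[i], id2 = ids[j], identity = pid,
                     score = score, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
    else data.frame(id1 = character(0), id2 = character(0),
                    identity = numeric(0), score = numeric(0))
  new("SimilarityNetwork", nodes = nodes, edges = edges,
      threshold = identityThreshold)
}

asIgraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net@edges[, c("id1", "id2")], directed = FALSE,
    vertices = net@nodes)
  if (nrow(net@edges)) {
    igraph::E(g)$identity <- net@edges$identity
    igraph::E(g)$score <- net@edges$score
  }
  g
}

#' Connected components of a similarity network
#'
#' @param net a [SimilarityNetwork-class].
#' @return list of character vectors (node ids, sorted), ordered by
#'   decreasing size then lexicographically by the first member.
#' @export
connectedComponents <- function(net) {
  comp <- igraph::components(asIgraph(net))
  sets <- split(names(comp$membership), comp$membership)
  sets <- lapply(sets, sort)
  sets[order(-vapply(sets, length, integer(1)),
             vapply(sets, `[`, character(1), 1))]
}

#' Cross-taxon affinity of a focal node set
#'
#' Summarizes the edges leaving a focal cluster: among edges with exactly
#' one focal endpoint, the fraction reaching each non-focal domain of life.
#' An isolated focal set (no outgoing edges) is reported as such.
#'
#' @param net a [SimilarityNetwork-class].
#' @param focalIds node ids of the focal set (must be nodes of the network).
#' @return list with `fractions` (named numeric summing to 1, or empty),
#'   `counts`, `nEdges` and `isolated`.
#' @export
crossTaxonAffinity <- function(net, focalIds) {
  if (!all(focalIds %in% net@nodes$id))
    stop("focalIds must all be network nodes")
  ed <- net@edges
  oneFocal <- xor(ed$id1 %in% focalIds, ed$id2 %in% focalIds)
  ed <- ed[oneFocal, , drop = FALSE]
  if (!nrow(ed))
    return(list(fractions = stats::setNames(numeric(0), character(0)),
                counts = stats::setNames(integer(0), character(0)),
                nEdges = 0L, isolated = TRUE))
  outer <- ifelse(ed$id1 %in% focalIds, ed$id2, ed$id1)
  dom <- net@nodes$domain_of_life[match(outer, net@nodes$id)]
  counts <- table(dom)
  fractions <- as.numeric(counts) / sum(counts)
  names(fractions) <- names(counts)
  list(fractions = fractions,
       counts = stats::setNames(as.integer(counts), names(counts)),
       nEdges = nrow(ed), isolated = FALSE)
}

#' Export a network as an edge-list TSV
#' @param net a [SimilarityNetwork-class].
#' @param path output path.
#' @export
writeEdgeListTsv <- function(net, path) {
  df <- net@edges
  names(df) <- c("id1", "id2", "pct_id", "score")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a network as GraphML with node attributes
#' @param net a [SimilarityNetwork-class].
#' @param path output path.
#' @export
writeGraphml <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}
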