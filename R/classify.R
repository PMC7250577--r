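# nested-vs-outgroup reading of a focal clade's placement

tipsOfNode <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
}

domainFraction <- function(tips, taxonomy, x) {
  if (!length(tips)) return(0)
  dom <- taxonomy$domain_of_life[match(tips, taxonomy$id)]
  mean(dom == x, na.rm = TRUE)
}

#' Classify the phylogenetic affinity of a focal clade
#'
#' Operationalizes the nested-vs-outgroup reading of a rooted tree that
#' distinguishes a horizontally acquired domain (nested inside a foreign
#' domain of life) from an ambiguous sister-group placement:
#' * `nested_in X` - the focal clade's sister group AND the next-closest
#'   outgroup are both composed (at least `compositionThreshold`) of taxa
#'   from domain of life X, and the sister group is not the set of all X
#'   taxa jointly;
#' * `outgroup_to X` - the sister group is exactly the clade of all X
#'   sequences in the tree;
#' * `unresolved` otherwise, including non-monophyletic focal sets (then
#'   the smallest clade containing the focal tips is reported).
#'
#' @param tree a `phylo`; rooted, or rootable via `outgroup`/midpoint.
#' @param focalIds tip labels of the focal set (must all be in the tree).
#' @param taxonomy data.frame with id and domain_of_life columns covering
#'   the tree tips.
#' @param outgroup optional tip labels to root on; when the tree is
#'   unrooted and no outgroup is given, midpoint rooting is used.
#' @param compositionThreshold sister/next-group purity required for a
#'   nested call (default 0.8).
#' @return list with `type` ("nested_in", "outgroup_to", "unresolved"),
#'   `taxon` (domain of life or NA), `sisterGroupTaxa`, `nextOutgroupTaxa`,
#'   `focalMonophyletic` and `containingClade`.
#' @export
classifyDomainAffinity <- function(tree, focalIds, taxonomy,
                                   outgroup = NULL,
                                   compositionThreshold = 0.8) {
  if (!all(focalIds %in% tree$tip.label))
    stop("focalIds must all be tips of the tree")
  if (!is.null(outgroup)) {
    outgroup <- intersect(outgroup, tree$tip.label)
    if (!length(outgroup)) stop("no outgroup tip present in the tree")
    tree <- tryCatch(
      ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
      error = function(e)
        ape::root(tree, outgroup = outgroup[1], resolve.root = TRUE))
  } else if (!ape::is.rooted(tree)) {
    tree <- phangorn::midpoint(tree)
  }
  ntip <- length(tree$tip.label)
  unresolvedCall <- function() {
    mrca <- if (length(focalIds) == 1L) match(focalIds, tree$tip.label)
      else ape::getMRCA(tree, focalIds)
    list(type = "unresolved", taxon = NA_character_,
         sisterGroupTaxa = character(0), nextOutgroupTaxa = character(0),
         focalMonophyletic = FALSE,
         containingClade = sort(tipsOfNode(tree, mrca)))
  }
  mono <- length(focalIds) == 1L ||
    ape::is.monophyletic(tree, focalIds)
  if (!mono) return(unresolvedCall())
  node <- if (length(focalIds) == 1L) match(focalIds, tree$tip.label)
    else ape::getMRCA(tree, focalIds)
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  if (!length(parent)) return(unresolvedCall()) # focal clade is the whole tree
  sibs <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], node)
  sisterTips <- sort(unique(unlist(lapply(sibs, tipsOfNode, tree = tree))))
  gp <- tree$edge[tree$edge[, 2] == parent, 1]
  nextTips <- if (length(gp)) {
    uncles <- setdiff(tree$edge[tree$edge[, 1] == gp, 2], parent)
    sort(unique(unlist(lapply(uncles, tipsOfNode, tree = tree))))
  } else character(0)
  base <- list(sisterGroupTaxa = sisterTips, nextOutgroupTaxa = nextTips,
               focalMonophyletic = TRUE, containingClade = sort(focalIds))
  for (x in setdiff(DOMAINS_OF_LIFE, "Unknown")) {
    allX <- sort(taxonomy$id[taxonomy$domain_of_life == x &
                               taxonomy$id %in% tree$tip.label])
    allX <- setdiff(allX, focalIds)
    if (!length(allX)) next
    if (identical(sisterTips, allX))
      return(c(list(type = "outgroup_to", taxon = x), base))
  }
  for (x in setdiff(DOMAINS_OF_LIFE, "Unknown")) {
    allX <- setdiff(
      sort(taxonomy$id[taxonomy$domain_of_life == x &
                         taxonomy$id %in% tree$tip.label]),
      focalIds)
    if (!length(allX)) next
    if (domainFraction(sisterTips, taxonomy, x) >= compositionThreshold &&
        length(nextTips) > 0 &&
        domainFraction(nextTips, taxonomy, x) >= compositionThreshold &&
        !identical(sisterTips, allX))
      return(c(list(type = "nested_in", taxon = x), base))
  }
  c(list(type = "unresolved", taxon = NA_character_), base)
}
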