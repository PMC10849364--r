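#' @import methods
#' @importFrom igraph is_directed is_simple gorder gsize V degree vertex_attr
NULL

setOldClass("igraph")

#' Melanoma risk-gene seed table
#'
#' The merged, unique list of disease risk genes with per-source provenance
#' flags. Each gene carries a nonempty subset of \{GWAS, familial, somatic\}.
#'
#' @slot table data.frame with columns \code{symbol} (unique, normalized) and
#'   logical columns \code{gwas}, \code{familial}, \code{somatic}.
#' @export
setClass("SeedTable", representation(table = "data.frame"))

setValidity("SeedTable", function(object) {
  tb <- object@table
  need <- c("symbol", "gwas", "familial", "somatic")
  if (!all(need %in% names(tb)))
    return(sprintf("table must have columns: %s", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$symbol))
    return("duplicated gene symbols in seed table")
  if (any(!nzchar(tb$symbol)))
    return("empty gene symbol")
  src <- as.matrix(tb[, c("gwas", "familial", "somatic")])
  if (!is.logical(src))
    return("source columns must be logical")
  if (nrow(tb) > 0 && any(rowSums(src) < 1))
    return("every seed gene must have at least one source")
  TRUE
})

#' Seeded protein-protein interaction network
#'
#' An undirected simple graph whose nodes are tagged \code{seed} (protein
#' product of a risk gene) or \code{bridge} (non-seed interactor mediating an
#' indirect seed-seed connection). Level zero contains seeds only; level one
#' adds bridges and their seed-incident edges.
#'
#' @slot graph igraph object with a \code{role} vertex attribute.
#' @slot level integer, 0 (seed-seed only) or 1 (seeds plus bridges).
#' @export
setClass("PpiNetwork", representation(graph = "igraph", level = "integer"))

setValidity("PpiNetwork", function(object) {
  g <- object@graph
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (!igraph::is_simple(g)) return("graph must be simple (no loops/multi-edges)")
  roles <- igraph::vertex_attr(g, "role")
  if (igraph::gorder(g) > 0 && (is.null(roles) || !all(roles %in% c("seed", "bridge"))))
    return("every node needs a role in {seed, bridge}")
  if (!object@level %in% c(0L, 1L)) return("level must be 0 or 1")
  if (object@level == 0L && any(roles == "bridge"))
    return("level-zero network cannot contain bridges")
  if (igraph::gorder(g) > 0 && any(roles == "bridge")) {
    ## definitional check: a bridge touches >= 2 seeds
    bidx <- which(roles == "bridge")
    for (i in bidx) {
      nb <- igraph::neighbors(g, i)
      if (sum(roles[as.integer(nb)] == "seed") < 2)
        return("bridge node with fewer than 2 seed neighbors")
    }
  }
  TRUE
})

#' Community partition of a network
#'
#' Result of greedy modularity maximization: a disjoint cover of the node set
#' together with the Newman-Girvan modularity Q of the final partition.
#'
#' @slot membership named integer vector, node -> community id (1-based,
#'   communities numbered by decreasing size).
#' @slot modularity numeric, Q of the partition on the clustered graph.
#' @export
setClass("ModularityPartition",
         representation(membership = "integer", modularity = "numeric"))

setValidity("ModularityPartition", function(object) {
  m <- object@membership
  if (length(m) > 0 && is.null(names(m))) return("membership must be named")
  if (anyDuplicated(names(m))) return("duplicate node names in membership")
  if (length(object@modularity) != 1) return("modularity must be a scalar")
  TRUE
})

#' Monte-Carlo overlap-enrichment result
#'
#' Observed overlap of a query gene set with the network-model gene set,
#' against a null of uniformly drawn same-size gene lists; the p-value is the
#' upper tail of a normal fitted to the simulated overlaps.
#'
#' @slot nOverlap observed overlap k.
#' @slot nQuery,nModel,nUniverse set sizes.
#' @slot nSims number of Monte-Carlo draws.
#' @slot nullMean,nullSd sample mean / sd (n-1 denominator) of the null draws.
#' @slot pNorm upper-tail normal p, 1 - Phi((k - mean)/sd).
#' @slot seed RNG seed used.
#' @slot degenerate TRUE when the null sd was zero.
#' @export
setClass("OverlapResult",
         representation(nOverlap = "integer", nQuery = "integer",
                        nModel = "integer", nUniverse = "integer",
                        nSims = "integer", nullMean = "numeric",
                        nullSd = "numeric", pNorm = "numeric",
                        seed = "integer", degenerate = "logical"))

setValidity("OverlapResult", function(object) {
  if (object@nOverlap < 0 ||
      object@nOverlap > min(object@nQuery, object@nModel))
    return("overlap outside [0, min(query, model)]")
  if (!is.na(object@pNorm) && (object@pNorm < 0 || object@pNorm > 1))
    return("pNorm outside [0, 1]")
  TRUE
})
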