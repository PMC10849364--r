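#' @include AllClasses.R
NULL

#' Accessors for melanet S4 containers
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{seedSymbols} returns the gene symbols of a [SeedTable-class],
#' \code{seedSources} its logical source matrix, \code{seedComposition} the
#' Venn composition counts; \code{networkGraph} returns the underlying igraph
#' of a [PpiNetwork-class], \code{nodeRoles} its node role vector and
#' \code{networkLevel} its level; \code{communityMembership} and
#' \code{modularityQ} expose a [ModularityPartition-class].
#'
#' @param object a melanet S4 object.
#' @return see Details per generic.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("seedSymbols", function(object) standardGeneric("seedSymbols"))

#' @rdname accessors
#' @export
setGeneric("seedSources", function(object) standardGeneric("seedSources"))

#' @rdname accessors
#' @export
setGeneric("seedComposition", function(object) standardGeneric("seedComposition"))

#' @rdname accessors
#' @export
setGeneric("networkGraph", function(object) standardGeneric("networkGraph"))

#' @rdname accessors
#' @export
setGeneric("nodeRoles", function(object) standardGeneric("nodeRoles"))

#' @rdname accessors
#' @export
setGeneric("networkLevel", function(object) standardGeneric("networkLevel"))

#' @rdname accessors
#' @export
setGeneric("communityMembership",
           function(object) standardGeneric("communityMembership"))

#' @rdname accessors
#' @export
setGeneric("modularityQ", function(object) standardGeneric("modularityQ"))

#' @rdname accessors
setMethod("seedSymbols", "SeedTable", function(object) object@table$symbol)

#' @rdname accessors
setMethod("seedSources", "SeedTable", function(object) {
  m <- as.matrix(object@table[, c("gwas", "familial", "somatic")])
  rownames(m) <- object@table$symbol
  m
})

#' @rdname accessors
setMethod("seedComposition", "SeedTable", function(object) {
  k <- rowSums(seedSources(object))
  c(single = sum(k == 1), double = sum(k == 2), triple = sum(k == 3),
    total = length(k))
})

#' @rdname accessors
setMethod("networkGraph", "PpiNetwork", function(object) object@graph)

#' @rdname accessors
setMethod("nodeRoles", "PpiNetwork", function(object) {
  r <- igraph::vertex_attr(object@graph, "role")
  names(r) <- igraph::V(object@graph)$name
  r
})

#' @rdname accessors
setMethod("networkLevel", "PpiNetwork", function(object) object@level)

#' @rdname accessors
setMethod("communityMembership", "ModularityPartition",
          function(object) object@membership)

#' @rdname accessors
setMethod("modularityQ", "ModularityPartition", function(object) object@modularity)

setMethod("show", "SeedTable", function(object) {
  comp <- seedComposition(object)
  cat("SeedTable with", comp[["total"]], "risk genes",
      sprintf("(%d single-, %d double-, %d triple-source)\n",
              comp[["single"]], comp[["double"]], comp[["triple"]]))
})

setMethod("show", "PpiNetwork", function(object) {
  roles <- nodeRoles(object)
  cat(sprintf("PpiNetwork level %d: %d nodes (%d seeds, %d bridges), %d edges\n",
              object@level, igraph::gorder(object@graph),
              sum(roles == "seed"), sum(roles == "bridge"),
              igraph::gsize(object@graph)))
})

setMethod("show", "ModularityPartition", function(object) {
  cat(sprintf("ModularityPartition: %d communities over %d nodes, Q = %.4f\n",
              length(unique(object@membership)), length(object@membership),
              object@modularity))
})

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf(
    "OverlapResult: k = %d (query %d, model %d, universe %d)\n  null mean %.3f, sd %.3f over %d sims; upper-tail normal p = %.3g%s\n",
    object@nOverlap, object@nQuery, object@nModel, object@nUniverse,
    object@nullMean, object@nullSd, object@nSims, object@pNorm,
    if (object@degenerate) " [degenerate null]" else ""))
})
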