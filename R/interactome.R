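#' @importFrom igraph graph_from_data_frame components induced_subgraph
#'   set_vertex_attr write_graph as_edgelist
NULL

.INTERACTION_COLS <- c("symbol_a", "symbol_b", "confidence")

#' Read a literature protein-interaction table
#'
#' Canonical dialect: TSV with columns \code{symbol_a}, \code{entrez_a},
#' \code{symbol_b}, \code{entrez_b}, \code{confidence} (in \[0,1\]),
#' \code{detection_methods} and \code{pubmed_ids} (';'-joined, possibly
#' empty). Optional 0/1 columns \code{ambiguous_mapping} and
#' \code{nonstandard_symbol} override the derived flags: a record is flagged
#' ambiguous when its entrez field lists several ids, and nonstandard when a
#' symbol does not look like an approved gene symbol after normalization.
#'
#' @param path file path.
#' @return data.frame of interaction records with normalized symbols and
#'   logical flag columns.
#' @export
readInteractions <- function(path) {
  df <- .readTsv(path, colClasses = "character")
  .assert(all(.INTERACTION_COLS %in% names(df)),
          sprintf("interaction table needs columns: %s",
                  paste(.INTERACTION_COLS, collapse = ", ")))
  df$confidence <- suppressWarnings(as.numeric(df$confidence))
  if (anyNA(df$confidence))
    stop("non-numeric confidence value in interaction table", call. = FALSE)
  if (any(df$confidence < 0 | df$confidence > 1))
    stop("confidence outside [0, 1] in interaction table", call. = FALSE)
  for (col in c("entrez_a", "entrez_b", "detection_methods", "pubmed_ids"))
    if (is.null(df[[col]])) df[[col]] <- ""
  if (!is.null(df$ambiguous_mapping))
    df$ambiguous_mapping <- df$ambiguous_mapping == "1"
  if (!is.null(df$nonstandard_symbol))
    df$nonstandard_symbol <- df$nonstandard_symbol == "1"
  .deriveInteractionFlags(df)
}

## normalize symbols and derive the ambiguous/nonstandard flags when absent
.deriveInteractionFlags <- function(df) {
  looksStandard <- function(s) grepl("^[A-Z][A-Z0-9-]*$", s)
  multiId <- function(e) grepl("[;,]", as.character(e))
  if (is.null(df$ambiguous_mapping))
    df$ambiguous_mapping <- multiId(df$entrez_a) | multiId(df$entrez_b)
  df$symbol_a <- normalizeSymbols(df$symbol_a)
  df$symbol_b <- normalizeSymbols(df$symbol_b)
  if (is.null(df$nonstandard_symbol))
    df$nonstandard_symbol <- !looksStandard(df$symbol_a) |
      !looksStandard(df$symbol_b)
  df
}

#' Write an interaction table in the canonical TSV dialect
#'
#' @param interactions interaction data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeInteractions <- function(interactions, path) {
  cols <- c("symbol_a", "entrez_a", "symbol_b", "entrez_b", "confidence",
            "detection_methods", "pubmed_ids")
  .assert(all(.INTERACTION_COLS %in% names(interactions)),
          "not an interaction table")
  for (col in cols) if (is.null(interactions[[col]])) interactions[[col]] <- ""
  .writeTsv(interactions[, cols], path)
}

#' Level-zero quality control of interaction records
#'
#' Keeps records backed by at least one PubMed identifier and by at least one
#' interaction-detection method other than "unspecified" (case-insensitive;
#' records whose only method is unspecified are low quality), and removes
#' self-interactions. Mirrors the manual curation applied to the direct
#' seed-seed download.
#'
#' @param interactions interaction data.frame, see [readInteractions()].
#' @param unspecified stop-list of method names treated as unspecified.
#' @return filtered data.frame.
#' @export
qcLevelZero <- function(interactions, unspecified = "unspecified") {
  hasPmid <- vapply(interactions$pubmed_ids,
                    function(x) length(.splitField(x)) > 0, logical(1))
  hasMethod <- vapply(interactions$detection_methods, function(x) {
    m <- tolower(.splitField(x))
    length(setdiff(m, tolower(unspecified))) > 0
  }, logical(1))
  notSelf <- interactions$symbol_a != interactions$symbol_b
  interactions[hasPmid & hasMethod & notSelf, , drop = FALSE]
}

#' High-confidence filter for the level-one download
#'
#' Keeps records with confidence at or above \code{threshold} (the 0.72
#' third-quartile "high confidence" cut; set \code{strictGt = TRUE} for a
#' strict comparison), removes any record touching an excluded promiscuous
#' partner (ubiquitin genes by default, whose interactions are unspecific),
#' removes records flagged as ambiguously mapped or carrying a nonstandard
#' symbol, and removes self-interactions.
#'
#' @param interactions interaction data.frame.
#' @param threshold confidence cut, default 0.72.
#' @param excludedPartners symbols whose records are dropped entirely.
#' @param strictGt if TRUE use confidence > threshold instead of >=.
#' @return filtered data.frame.
#' @export
filterHighConfidence <- function(interactions, threshold = 0.72,
                                 excludedPartners = c("UBB", "UBC", "UBD"),
                                 strictGt = FALSE) {
  keep <- if (strictGt) interactions$confidence > threshold
          else interactions$confidence >= threshold
  excludedPartners <- normalizeSymbols(excludedPartners)
  keep <- keep &
    !(interactions$symbol_a %in% excludedPartners) &
    !(interactions$symbol_b %in% excludedPartners) &
    !interactions$ambiguous_mapping & !interactions$nonstandard_symbol &
    interactions$symbol_a != interactions$symbol_b
  interactions[keep, , drop = FALSE]
}

## unique unordered seed pairs / edges from interaction rows
.edgePairs <- function(interactions) {
  if (nrow(interactions) == 0)
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  a <- pmin(interactions$symbol_a, interactions$symbol_b)
  b <- pmax(interactions$symbol_a, interactions$symbol_b)
  unique(data.frame(a = a, b = b, stringsAsFactors = FALSE)[a != b, ])
}

.seedVector <- function(seeds) {
  if (is(seeds, "SeedTable")) seedSymbols(seeds) else normalizeSymbols(seeds)
}

.componentReport <- function(g) {
  cmp <- igraph::components(g)
  members <- split(names(cmp$membership), cmp$membership)
  members <- lapply(members, sort)
  ## rank by size desc, ties by smallest lexicographic member
  ord <- order(-vapply(members, length, integer(1)),
               vapply(members, `[`, character(1), 1))
  members <- members[ord]
  data.frame(component = seq_along(members),
             n_nodes = vapply(members, length, integer(1)),
             members = vapply(members, paste, character(1), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Build the level-zero (seed-seed) network
#'
#' Restricts the (already quality-controlled) interaction set to edges whose
#' both endpoints are seeds. All seeds appear as nodes; seeds without any
#' seed-seed edge are reported as isolated. The largest connected component
#' is the core-level-zero network.
#'
#' @param seeds a [SeedTable-class] or character vector of seed symbols.
#' @param interactions interaction data.frame after [qcLevelZero()].
#' @return list with \code{network} (a level-0 [PpiNetwork-class] over all
#'   seeds), \code{report} (non-singleton connected components, largest
#'   first, ties broken by smallest member), \code{core} (symbols of the
#'   largest component) and \code{isolated} (seeds with no seed-seed edge).
#' @export
buildLevelZero <- function(seeds, interactions) {
  seeds <- .seedVector(seeds)
  pr <- .edgePairs(interactions)
  pr <- pr[pr$a %in% seeds & pr$b %in% seeds, , drop = FALSE]
  g <- igraph::graph_from_data_frame(pr, directed = FALSE,
                                     vertices = data.frame(name = sort(seeds)))
  g <- igraph::set_vertex_attr(g, "role", value = "seed")
  net <- new("PpiNetwork", graph = g, level = 0L)
  rep <- .componentReport(g)
  isolated <- sort(unlist(strsplit(
    rep$members[rep$n_nodes == 1], ";", fixed = TRUE), use.names = FALSE))
  rep <- rep[rep$n_nodes > 1, , drop = FALSE]
  rep$component <- seq_len(nrow(rep))
  core <- if (nrow(rep) > 0) strsplit(rep$members[1], ";")[[1]] else character(0)
  list(network = net, report = rep, core = core, isolated = isolated)
}

#' Identify bridge interactors
#'
#' A non-seed protein X is a bridge when, among its seed neighbors, at least
#' one pair of seeds is not already directly connected in the (filtered)
#' interaction set: X then mediates an indirect seed-seed path of length 2.
#' For candidates touching three or more seeds, one unconnected pair
#' suffices.
#'
#' @param seeds a [SeedTable-class] or character vector.
#' @param interactions interaction data.frame after [filterHighConfidence()].
#' @return sorted character vector of bridge symbols.
#' @export
findBridges <- function(seeds, interactions) {
  seeds <- .seedVector(seeds)
  pr <- .edgePairs(interactions)
  seedEdge <- pr[pr$a %in% seeds & pr$b %in% seeds, , drop = FALSE]
  seedEdgeKey <- paste(seedEdge$a, seedEdge$b, sep = "\r")
  ## seed neighbors of every non-seed node
  touching <- pr[xor(pr$a %in% seeds, pr$b %in% seeds), , drop = FALSE]
  nonseed <- ifelse(touching$a %in% seeds, touching$b, touching$a)
  seed <- ifelse(touching$a %in% seeds, touching$a, touching$b)
  nbrs <- split(seed, nonseed)
  isBridge <- vapply(nbrs, function(ss) {
    ss <- sort(unique(ss))
    if (length(ss) < 2) return(FALSE)
    for (i in seq_len(length(ss) - 1))
      for (j in seq(i + 1, length(ss)))
        if (!(paste(ss[i], ss[j], sep = "\r") %in% seedEdgeKey)) return(TRUE)
    FALSE
  }, logical(1))
  sort(names(nbrs)[isBridge])
}

#' Build the level-one (seed-plus-bridge) network
#'
#' The level-one graph contains every seed-seed edge of the high-confidence
#' interaction set plus every seed-bridge edge for the bridges returned by
#' [findBridges()]; bridge-bridge edges are excluded and non-bridge non-seed
#' interactors are dropped. The largest connected component is the
#' core-first-level network, i.e. the disease model.
#'
#' @param seeds a [SeedTable-class] or character vector.
#' @param interactions interaction data.frame after [filterHighConfidence()].
#' @return list with \code{network} (level-1 [PpiNetwork-class] over all
#'   seeds and bridges), \code{core} (the largest-component subnetwork, also
#'   a [PpiNetwork-class]), \code{report} (component census), \code{bridges}
#'   (bridge symbols) and \code{isolated} (seeds unreachable at level one).
#' @export
buildLevelOne <- function(seeds, interactions) {
  seeds <- .seedVector(seeds)
  bridges <- findBridges(seeds, interactions)
  pr <- .edgePairs(interactions)
  seedSeed <- pr[pr$a %in% seeds & pr$b %in% seeds, , drop = FALSE]
  seedBridge <- pr[(pr$a %in% seeds & pr$b %in% bridges) |
                   (pr$b %in% seeds & pr$a %in% bridges), , drop = FALSE]
  edges <- rbind(seedSeed, seedBridge)
  verts <- sort(unique(c(seeds, bridges)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = verts))
  roles <- ifelse(verts %in% seeds, "seed", "bridge")
  g <- igraph::set_vertex_attr(g, "role", value = roles)
  net <- new("PpiNetwork", graph = g, level = 1L)
  rep <- .componentReport(g)
  isolated <- sort(unlist(strsplit(
    rep$members[rep$n_nodes == 1], ";", fixed = TRUE), use.names = FALSE))
  rep <- rep[rep$n_nodes > 1, , drop = FALSE]
  rep$component <- seq_len(nrow(rep))
  core <- net
  if (nrow(rep) > 0) {
    coreNodes <- strsplit(rep$members[1], ";")[[1]]
    core <- new("PpiNetwork",
                graph = igraph::induced_subgraph(g, coreNodes), level = 1L)
  }
  list(network = net, core = core, report = rep, bridges = bridges,
       isolated = isolated)
}

#' Hub nodes of a network
#'
#' Nodes carrying at least \code{minDegree} edges, ranked by decreasing
#' degree with lexicographic tie-break. The published model calls its 19
#' highest-degree proteins (14 to 41 edges) hubs.
#'
#' @param network a [PpiNetwork-class].
#' @param minDegree minimum degree, default 14.
#' @return data.frame with \code{symbol}, \code{degree}, \code{role}.
#' @export
hubNodes <- function(network, minDegree = 14) {
  stopifnot(is(network, "PpiNetwork"))
  g <- networkGraph(network)
  deg <- igraph::degree(g)
  roles <- nodeRoles(network)
  keep <- names(deg)[deg >= minDegree]
  keep <- keep[order(-deg[keep], keep)]
  data.frame(symbol = keep, degree = as.integer(deg[keep]),
             role = unname(roles[keep]), stringsAsFactors = FALSE)
}

#' Serialize / restore a network as edge-list + node-attribute TSVs
#'
#' @param network a [PpiNetwork-class].
#' @param edgePath path of the edge-list TSV (node_a, node_b, role_a, role_b).
#' @param nodePath path of the node-attribute TSV (node, role).
#' @return \code{writePpiNetwork} returns paths invisibly;
#'   \code{readPpiNetwork} a [PpiNetwork-class].
#' @export
writePpiNetwork <- function(network, edgePath, nodePath) {
  stopifnot(is(network, "PpiNetwork"))
  g <- networkGraph(network)
  roles <- nodeRoles(network)
  el <- igraph::as_edgelist(g)
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  ord <- order(a, b)
  edges <- data.frame(node_a = a[ord], node_b = b[ord],
                      role_a = unname(roles[a[ord]]),
                      role_b = unname(roles[b[ord]]))
  .writeTsv(edges, edgePath)
  nodes <- data.frame(node = sort(names(roles)),
                      role = unname(roles[sort(names(roles))]))
  .writeTsv(nodes, nodePath)
  invisible(c(edgePath, nodePath))
}

#' @rdname writePpiNetwork
#' @param level network level (0 or 1) of the restored object.
#' @export
readPpiNetwork <- function(edgePath, nodePath, level = 1L) {
  edges <- .readTsv(edgePath)
  nodes <- .readTsv(nodePath)
  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes$node))
  g <- igraph::set_vertex_attr(g, "role", value = nodes$role)
  new("PpiNetwork", graph = g, level = as.integer(level))
}

#' Export a network as GraphML for viewers
#'
#' @param network a [PpiNetwork-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
exportGraphML <- function(network, path) {
  stopifnot(is(network, "PpiNetwork"))
  igraph::write_graph(networkGraph(network), path, format = "graphml")
  invisible(path)
}
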