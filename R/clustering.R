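#' Greedy modularity community detection
#'
#' Agglomerative (fast-greedy) modularity maximization: starting from
#' singleton communities, the pair of connected communities with the largest
#' modularity gain dQ is merged repeatedly until no merge has dQ > 0.
#' Tie-breaking is deterministic: among merges with equal gain (within 1e-12)
#' the pair with the smallest lexicographic (min community label, max
#' community label) key is chosen, where a community's label is its smallest
#' member name, so partitions are bit-reproducible. Isolated nodes end up as
#' singleton clusters. The modularity of the final partition is computed with
#' \code{igraph::modularity}.
#'
#' @param network a [PpiNetwork-class] or an undirected simple igraph with
#'   named vertices.
#' @return a [ModularityPartition-class]; communities are numbered by
#'   decreasing size (ties by smallest member).
#' @export
greedyModularity <- function(network) {
  g <- if (is(network, "PpiNetwork")) networkGraph(network) else network
  stopifnot(inherits(g, "igraph"))
  .assert(!igraph::is_directed(g), "graph must be undirected")
  .assert(igraph::gorder(g) > 0, "empty graph")
  .assert(igraph::gsize(g) > 0, "graph must have at least one edge")
  .assert(igraph::is_simple(g), "graph must be simple")
  nodes <- igraph::V(g)$name
  .assert(!is.null(nodes) && !anyDuplicated(nodes), "vertices must be uniquely named")

  n <- length(nodes)
  m <- igraph::gsize(g)
  el <- igraph::as_edgelist(g, names = FALSE)

  ## W: symmetric community-pair edge counts, diagonal doubled (2 * intra)
  W <- matrix(0, n, n)
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    W[i, j] <- W[i, j] + 1
    W[j, i] <- W[j, i] + 1
  }
  D <- as.numeric(igraph::degree(g))
  active <- rep(TRUE, n)
  label <- nodes                       # smallest member name per community
  members <- as.list(nodes)

  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    sub <- W[idx, idx, drop = FALSE]
    cand <- which(upper.tri(sub) & sub > 0, arr.ind = TRUE)
    if (nrow(cand) == 0) break
    ci <- idx[cand[, 1]]; cj <- idx[cand[, 2]]
    dq <- W[cbind(ci, cj)] / m - D[ci] * D[cj] / (2 * m^2)
    best <- max(dq)
    if (best <= 0) break
    tied <- which(dq >= best - 1e-12)
    la <- pmin(label[ci[tied]], label[cj[tied]])
    lb <- pmax(label[ci[tied]], label[cj[tied]])
    pick <- tied[order(la, lb)[1]]
    a <- ci[pick]; b <- cj[pick]
    ## merge b into a
    W[a, ] <- W[a, ] + W[b, ]
    W[, a] <- W[, a] + W[, b]
    W[b, ] <- 0; W[, b] <- 0
    D[a] <- D[a] + D[b]
    members[[a]] <- c(members[[a]], members[[b]])
    label[a] <- min(label[a], label[b])
    active[b] <- FALSE
  }

  comm <- members[active]
  comm <- lapply(comm, sort)
  ord <- order(-vapply(comm, length, integer(1)),
               vapply(comm, `[`, character(1), 1))
  comm <- comm[ord]
  membership <- integer(n)
  names(membership) <- nodes
  for (k in seq_along(comm)) membership[comm[[k]]] <- k
  q <- igraph::modularity(g, membership[nodes])
  new("ModularityPartition", membership = membership, modularity = q)
}

#' Cluster quality control
#'
#' A cluster passes QC when it has at least \code{minNodes} nodes and its
#' seed:bridge ratio is at least \code{minRatio} (default 0.7). A cluster
#' with zero bridges is maximally seed-enriched and passes the ratio
#' criterion (ratio +Inf).
#'
#' @param partition a [ModularityPartition-class].
#' @param roles named character vector (node -> "seed"/"bridge"), e.g.
#'   \code{nodeRoles(network)}.
#' @param minNodes minimum cluster size, default 10.
#' @param minRatio minimum seed:bridge ratio, default 0.7.
#' @return data.frame with \code{cluster_id}, \code{n_nodes}, \code{n_seeds},
#'   \code{n_bridges}, \code{seed_bridge_ratio}, \code{passed_qc}.
#' @export
qcClusters <- function(partition, roles, minNodes = 10, minRatio = 0.7) {
  stopifnot(is(partition, "ModularityPartition"))
  mem <- communityMembership(partition)
  .assert(all(names(mem) %in% names(roles)), "roles missing for some nodes")
  ids <- sort(unique(mem))
  out <- do.call(rbind, lapply(ids, function(k) {
    nd <- names(mem)[mem == k]
    ns <- sum(roles[nd] == "seed")
    nb <- sum(roles[nd] == "bridge")
    ratio <- if (nb == 0) Inf else ns / nb
    data.frame(cluster_id = k, n_nodes = length(nd), n_seeds = ns,
               n_bridges = nb, seed_bridge_ratio = ratio,
               passed_qc = length(nd) >= minNodes && ratio >= minRatio)
  }))
  out
}
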