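## Independent brute-force oracles used across the suite. These deliberately
## re-derive results with plain loops / enumeration, never through the
## package's own code paths.

## bridge definition checked pair-by-pair over an explicit edge list
bruteBridges <- function(seeds, edges) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  seedEdges <- edges[edges$a %in% seeds & edges$b %in% seeds, , drop = FALSE]
  seedKeys <- key(seedEdges$a, seedEdges$b)
  nodes <- setdiff(unique(c(edges$a, edges$b)), seeds)
  out <- character(0)
  for (x in nodes) {
    nb <- unique(c(edges$b[edges$a == x], edges$a[edges$b == x]))
    nb <- intersect(nb, seeds)
    if (length(nb) < 2) next
    found <- FALSE
    for (i in seq_len(length(nb) - 1))
      for (j in seq(i + 1, length(nb)))
        if (!(key(nb[i], nb[j]) %in% seedKeys)) found <- TRUE
    if (found) out <- c(out, x)
  }
  sort(out)
}

## Venn composition by direct membership counting
bruteComposition <- function(l1, l2, l3) {
  all <- sort(unique(c(l1, l2, l3)))
  k <- vapply(all, function(g)
    sum(g %in% l1, g %in% l2, g %in% l3), numeric(1))
  c(single = sum(k == 1), double = sum(k == 2), triple = sum(k == 3),
    total = length(all))
}

## all leaf modularities reachable by exhaustively branching over every
## maximal-gain greedy merge (tie branches explored in full)
exhaustiveGreedyQ <- function(g) {
  m <- igraph::gsize(g)
  W <- as.matrix(igraph::as_adjacency_matrix(g))
  diag(W) <- 0
  D <- rowSums(W)
  leaves <- numeric(0)
  rec <- function(W, D, q) {
    k <- nrow(W)
    best <- -Inf; pairs <- list()
    if (k >= 2) {
      for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
        if (W[i, j] <= 0) next
        dq <- W[i, j] / m - D[i] * D[j] / (2 * m^2)
        if (dq > best + 1e-12) { best <- dq; pairs <- list(c(i, j)) }
        else if (abs(dq - best) <= 1e-12) pairs[[length(pairs) + 1]] <- c(i, j)
      }
    }
    if (length(pairs) == 0 || best <= 0) { leaves <<- c(leaves, q); return() }
    for (pr in pairs) {
      i <- pr[1]; j <- pr[2]
      W2 <- W
      W2[i, ] <- W2[i, ] + W2[j, ]
      W2[, i] <- W2[, i] + W2[, j]
      W2 <- W2[-j, -j, drop = FALSE]
      D2 <- D; D2[i] <- D2[i] + D2[j]; D2 <- D2[-j]
      rec(W2, D2, q + best)
    }
  }
  rec(W, D, -sum(D^2) / (4 * m^2))
  leaves
}

## plain union-find over term ids
unionFindComponents <- function(ids, parent, child) {
  up <- stats::setNames(ids, ids)
  find <- function(x) { while (up[[x]] != x) x <- up[[x]]; x }
  for (i in seq_along(parent)) {
    if (!(parent[i] %in% ids) || !(child[i] %in% ids)) next
    rp <- find(parent[i]); rc <- find(child[i])
    if (rp != rc) up[[rc]] <- rp
  }
  roots <- vapply(ids, find, character(1))
  unname(lapply(split(ids, roots), sort))
}

## exact hypergeometric upper tail P(X >= k) by term-by-term summation
hyperTailSum <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

## random named simple graph
randomNamedGraph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}
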