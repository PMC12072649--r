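## Independent brute-force oracles used across the suite. These are
## deliberately naive (BFS + explicit shortest-path enumeration, direct
## textbook formulas) and share no code with the package internals.

## random connected undirected simple graph with named nodes
randomConnectedGraph <- function(n, p = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    ig <- igraph::sample_gnp(n, p)
    if (igraph::components(ig)$no == 1) break
  }
  igraph::V(ig)$name <- sprintf("n%02d", seq_len(n))
  GeneGraph(ig)
}

## BFS distances from one source on an adjacency matrix
.bfsDist <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(A[v, ] > 0)
      newly <- nb[d[nb] == Inf]
      d[newly] <- d[v] + 1
      nxt <- c(nxt, newly)
    }
    frontier <- unique(nxt)
  }
  d
}

## all shortest paths between s and t as a list of vertex index vectors
.allShortestPaths <- function(A, D, s, t) {
  if (s == t) return(list(s))
  pred <- which(A[, t] > 0 & D[s, ] == D[s, t] - 1)
  out <- list()
  for (u in pred)
    for (pth in .allShortestPaths(A, D, s, u))
      out[[length(out) + 1]] <- c(pth, t)
  out
}

## all ten metrics by enumeration / direct formulas
oracleCentralities <- function(g) {
  A <- adjacencyMatrix(g)
  n <- nrow(A)
  D <- t(vapply(seq_len(n), function(s) .bfsDist(A, s), numeric(n)))
  btw <- numeric(n)
  str <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- .allShortestPaths(A, D, s, t)
    through <- table(factor(unlist(lapply(paths, function(p)
      p[-c(1, length(p))])), levels = seq_len(n)))
    btw <- btw + as.numeric(through) / length(paths)
    str <- str + as.numeric(through)
  }
  deg <- rowSums(A)
  clus <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    e <- sum(A[nb, nb]) / 2
    2 * e / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  nbc <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (!length(nb)) 0 else mean(deg[nb])
  }, numeric(1))
  diamG <- max(D)
  topo <- vapply(seq_len(n), function(i) {
    if (deg[i] <= 1) return(0)
    js <- setdiff(seq_len(n), i)
    vals <- c()
    for (j in js) {
      shared <- sum(A[i, ] > 0 & A[j, ] > 0)
      if (shared > 0) vals <- c(vals, (shared + A[i, j]) / deg[i])
    }
    if (is.null(vals)) 0 else mean(vals)
  }, numeric(1))
  data.frame(
    degree = deg,
    betweenness = btw,
    closeness = 1 / rowSums(D),
    clustering = clus,
    neighborhood_connectivity = nbc,
    radiality = (diamG + 1) - rowSums(D) / (n - 1),
    eccentricity = apply(D, 1, max),
    avg_shortest_path = rowSums(D) / (n - 1),
    stress = str,
    topological_coefficient = topo,
    row.names = nodeNames(g)
  )
}

## textbook Pearson correlation
oraclePearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

## two 4-cliques joined by a single bridge edge, the canonical
## two-community graph
bridgedCliques <- function() {
  ig <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  ig <- igraph::add_edges(ig, c(1, 5))
  igraph::V(ig)$name <- letters[1:8]
  GeneGraph(ig)
}

## best two-community modularity over all sign vectors (exhaustive)
enumerateBestBisection <- function(g) {
  B <- modularityMatrix(g)
  m <- numEdges(g)
  n <- numNodes(g)
  best <- -Inf
  bestS <- NULL
  for (mask in 0:(2^n - 1)) {
    s <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, 1, -1)
    q <- as.numeric(t(s) %*% B %*% s) / (4 * m)
    if (q > best) { best <- q; bestS <- s }
  }
  list(Q = best, s = setNames(bestS, nodeNames(g)))
}
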