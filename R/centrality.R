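#' Compute the ten topological centrality metrics
#'
#' Computes, for every node of a connected gene network: degree,
#' betweenness (unnormalized shortest-path counts over unordered
#' source-target pairs), closeness (reciprocal of the summed shortest-path
#' distances), local clustering coefficient, neighborhood connectivity
#' (mean neighbor degree), radiality, eccentricity, average shortest path
#' length, stress (count of shortest paths passing through the node), and
#' the topological coefficient.
#'
#' Degree, betweenness, closeness, clustering, eccentricity and
#' neighbor-degree come from igraph; stress, radiality and the topological
#' coefficient are computed here (no igraph equivalent exists). Clustering
#' of degree 0/1 nodes is defined as 0; nodes with degree <= 1 get
#' topological coefficient 0.
#'
#' @param g a connected [GeneGraph-class] with at least 3 nodes.
#' @return a [CentralityTable-class].
#' @examples
#' ct <- computeCentralities(GeneGraph(cbind(c("a", "b"), c("b", "c"))))
#' centralityMetrics(ct)["b", ]
#' @export
computeCentralities <- function(g) {
  stopifnot(is(g, "GeneGraph"))
  n <- numNodes(g)
  if (n < 3) stop("centrality analysis requires at least 3 nodes")
  .assertConnected(g, "distance-based centrality")
  ig <- g@graph
  nm <- nodeNames(g)
  A <- adjacencyMatrix(g)

  deg <- igraph::degree(ig)
  btw <- igraph::betweenness(ig, directed = FALSE, normalized = FALSE)
  D <- igraph::distances(ig)
  sumD <- rowSums(D)
  clo <- 1 / sumD
  clus <- igraph::transitivity(ig, type = "local", isolates = "zero")
  clus[!is.finite(clus)] <- 0
  nbc <- as.numeric(A %*% deg) / pmax(deg, 1)
  diamG <- max(D)
  ecc <- apply(D, 1, max)
  L <- sumD / (n - 1)
  radiality <- ((diamG + 1) * (n - 1) - sumD) / (n - 1)

  sigma <- .allPairsPathCounts(A, D)
  stress <- .stressFromCounts(D, sigma)
  topo <- .topologicalCoefficient(A, deg)

  m <- cbind(
    degree = deg, betweenness = btw, closeness = clo, clustering = clus,
    neighborhood_connectivity = nbc, radiality = radiality,
    eccentricity = ecc, avg_shortest_path = L, stress = stress,
    topological_coefficient = topo
  )
  rownames(m) <- nm
  new("CentralityTable", metrics = m)
}

## Number of shortest paths between every node pair, by level-ordered
## dynamic programming over the BFS DAG from each source.
.allPairsPathCounts <- function(A, D) {
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sig <- numeric(n)
    sig[s] <- 1
    ds <- D[s, ]
    for (d in seq_len(max(ds))) {
      lev <- which(ds == d)
      if (!length(lev)) break
      prev <- which(ds == d - 1)
      ## paths to v = sum of paths to predecessors (neighbors one level up)
      sig[lev] <- as.numeric(A[lev, prev, drop = FALSE] %*% sig[prev])
    }
    sigma[s, ] <- sig
  }
  sigma
}

## stress_i = sum over unordered pairs {s,t}, s != i != t, of the number of
## shortest s-t paths through i: sigma(s,i) * sigma(i,t) when i lies on a
## shortest s-t path.
.stressFromCounts <- function(D, sigma) {
  n <- nrow(D)
  out <- numeric(n)
  for (i in seq_len(n)) {
    onPath <- outer(D[, i], D[i, ], "+") == D
    cnt <- outer(sigma[, i], sigma[i, ]) * onPath
    cnt[i, ] <- 0
    cnt[, i] <- 0
    diag(cnt) <- 0
    out[i] <- sum(cnt) / 2
  }
  out
}

## T_i = mean over nodes j (j != i) sharing at least one neighbor with i of
## J(i,j)/k_i, with J(i,j) = #shared neighbors, +1 if i and j are adjacent.
## Nodes with degree <= 1 are assigned 0.
.topologicalCoefficient <- function(A, deg) {
  n <- nrow(A)
  shared <- A %*% A
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (deg[i] <= 1) next
    js <- which(shared[i, ] > 0)
    js <- js[js != i]
    if (!length(js)) next
    out[i] <- mean(shared[i, js] + A[i, js]) / deg[i]
  }
  out
}

#' @describeIn computeCentralities extract the metric table as a data.frame
#'   (node ids in rownames).
#' @param ct a `CentralityTable`.
#' @export
centralityMetrics <- function(ct) {
  stopifnot(is(ct, "CentralityTable"))
  as.data.frame(ct@metrics)
}

setMethod("show", "CentralityTable", function(object) {
  cat(sprintf("CentralityTable: %d nodes x %d metrics\n",
              nrow(object@metrics), ncol(object@metrics)))
  print(head(round(object@metrics, 3), 5))
  if (nrow(object@metrics) > 5) cat("...\n")
})
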