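#' Modularity matrix of a gene network
#'
#' The full modularity matrix has entries `B_ij = A_ij - k_i k_j / (2m)`,
#' the deviation of the observed adjacency from the degree-preserving
#' random expectation; every row sums to zero. For a node subset the
#' *generalized* matrix used by recursive splitting is returned:
#' `Bg_ij = B_ij - delta_ij * sum_{k in g} B_ik`, which keeps modularity
#' gains additive across recursive bisections.
#'
#' @param g a [GeneGraph-class].
#' @param nodes optional character vector (subset); `NULL` means the full
#'   matrix.
#' @return numeric matrix with node-name dimnames.
#' @export
modularityMatrix <- function(g, nodes = NULL) {
  stopifnot(is(g, "GeneGraph"))
  if (numNodes(g) == 0) stop("empty graph")
  A <- adjacencyMatrix(g)
  k <- rowSums(A)
  m <- sum(k) / 2
  if (m == 0) stop("graph has no edges")
  B <- A - outer(k, k) / (2 * m)
  if (is.null(nodes)) return(B)
  if (!length(nodes)) stop("node subset must be nonempty")
  idx <- match(nodes, rownames(B))
  if (anyNA(idx)) stop("unknown node(s): ", paste(nodes[is.na(idx)], collapse = ", "))
  Bg <- B[idx, idx, drop = FALSE]
  diag(Bg) <- diag(Bg) - rowSums(Bg)
  Bg
}

#' Modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * [c_i == c_j]`. The
#' single-community partition always has Q = 0; for a two-community
#' partition encoded as a sign vector `s`, Q equals `s' B s / (4m)`.
#'
#' @param g a [GeneGraph-class].
#' @param partition a [Partition-class] or a named membership vector
#'   covering every node of `g`.
#' @return modularity Q (scalar in `[-1, 1]`).
#' @export
modularityQ <- function(g, partition) {
  stopifnot(is(g, "GeneGraph"))
  mem <- if (is(partition, "Partition")) partition@membership else partition
  nm <- nodeNames(g)
  if (!all(nm %in% names(mem)))
    stop("node(s) missing a community label: ",
         paste(head(setdiff(nm, names(mem)), 5), collapse = ", "))
  lab <- mem[nm]
  A <- adjacencyMatrix(g)
  k <- rowSums(A)
  m <- sum(k) / 2
  if (m == 0) stop("graph has no edges")
  same <- outer(lab, lab, "==")
  sum((A - outer(k, k) / (2 * m)) * same) / (2 * m)
}

## Leading eigenpair of a symmetric matrix. Dense solver up to 500 nodes;
## shifted power iteration (deterministic start) above that.
.leadingEigSym <- function(M, tol = 1e-9) {
  n <- nrow(M)
  if (n <= 500) {
    e <- eigen(M, symmetric = TRUE)
    return(list(value = e$values[1], vector = e$vectors[, 1]))
  }
  shift <- max(rowSums(abs(M)))  # Gershgorin bound: M + shift*I is PSD
  v <- rep(1, n) + seq_len(n) / n  # deterministic, not orthogonal to much
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (it in seq_len(10000)) {
    w <- as.numeric(M %*% v) + shift * v
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    w <- w / nw
    lamNew <- as.numeric(crossprod(w, M %*% w))
    if (abs(lamNew - lam) < tol && sum(abs(w - v)) < tol * n) {
      v <- w; lam <- lamNew; break
    }
    v <- w; lam <- lamNew
  }
  list(value = lam, vector = v)
}

## Kernighan-Lin style vertex-moving refinement of a sign split (the
## fine-tuning stage of the classical spectral modularity method): in each
## pass every vertex is flipped once, in greedy order of modularity gain,
## and the best intermediate configuration is kept; passes repeat while
## they improve the objective s' Bg s.
.klRefine <- function(Bg, s, maxPasses = 20) {
  n <- length(s)
  obj <- as.numeric(crossprod(s, Bg %*% s))
  for (pass in seq_len(maxPasses)) {
    Bs <- as.numeric(Bg %*% s)
    sCur <- s
    objCur <- obj
    moved <- logical(n)
    bestObj <- obj
    bestS <- s
    for (step in seq_len(n)) {
      ## gain of flipping i: 4 * (B_ii - s_i * (Bs)_i)
      gains <- 4 * (diag(Bg) - sCur * Bs)
      gains[moved] <- -Inf
      i <- which.max(gains)
      objCur <- objCur + gains[i]
      Bs <- Bs - 2 * sCur[i] * Bg[, i]
      sCur[i] <- -sCur[i]
      moved[i] <- TRUE
      if (objCur > bestObj + 1e-12) {
        bestObj <- objCur
        bestS <- sCur
      }
    }
    if (bestObj <= obj + 1e-12) break
    s <- bestS
    obj <- bestObj
  }
  s
}

#' Leading-eigenvector bisection of a node subset
#'
#' Computes the eigenvector of the (generalized) modularity matrix with the
#' largest eigenvalue and assigns each node to one of two groups by the
#' sign of its component (`v_i >= 0` maps to +1), followed by the
#' classical vertex-moving fine-tuning stage (greedy single-vertex flips,
#' Kernighan-Lin style) that polishes the spectral split. The split is
#' declared indivisible when the leading eigenvalue is not positive
#' (within tolerance) or when the modularity gain of the refined split is
#' not positive.
#'
#' @param g a [GeneGraph-class].
#' @param nodes node subset to split (default: all nodes).
#' @param tol eigenvalue tolerance for indivisibility.
#' @param refine apply the vertex-moving fine-tuning stage (default TRUE).
#' @return list with `s` (named +1/-1 vector), `dQ` (modularity gain),
#'   `lambda` (leading eigenvalue) and `divisible` (logical).
#' @export
leadingEigenBisect <- function(g, nodes = nodeNames(g), tol = 1e-9,
                               refine = TRUE) {
  stopifnot(is(g, "GeneGraph"))
  if (length(nodes) < 2) stop("subset must contain at least 2 nodes")
  Bg <- modularityMatrix(g, nodes)
  eig <- .leadingEigSym(Bg, tol)
  if (!all(is.finite(eig$vector))) stop("eigen-solver failed on the modularity matrix")
  s <- ifelse(eig$vector >= 0, 1, -1)
  names(s) <- nodes
  m <- numEdges(g)
  divisibleSpectral <- eig$value > tol
  if (refine && divisibleSpectral) s <- .klRefine(Bg, s)
  dQ <- as.numeric(crossprod(s, Bg %*% s)) / (4 * m)
  divisible <- divisibleSpectral && dQ > 1e-12 && length(unique(s)) == 2
  list(s = s, dQ = dQ, lambda = eig$value, divisible = divisible)
}

#' Detect communities by recursive leading-eigenvector splitting
#'
#' Greedy recursive bisection: at each step the candidate split with the
#' largest positive modularity gain (over all current communities) is
#' applied, until no split improves modularity (gain <= 1e-12) or `maxK`
#' communities exist. Labels are relabeled `0..K-1` by decreasing
#' community size.
#'
#' @param g a connected [GeneGraph-class].
#' @param maxK maximum number of communities (>= 1).
#' @return a [Partition-class] with modularity `Q`.
#' @examples
#' gr <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
#' gr <- igraph::add_edges(gr, c(1, 5))
#' igraph::V(gr)$name <- letters[1:8]
#' detectCommunities(GeneGraph(gr))
#' @export
detectCommunities <- function(g, maxK = Inf) {
  stopifnot(is(g, "GeneGraph"))
  if (maxK < 1) stop("maxK must be >= 1")
  .assertConnected(g, "community detection")
  comms <- list(nodeNames(g))
  splits <- list(if (length(comms[[1]]) >= 2) leadingEigenBisect(g, comms[[1]]) else NULL)
  while (length(comms) < maxK) {
    gains <- vapply(splits, function(sp)
      if (!is.null(sp) && sp$divisible) sp$dQ else -Inf, numeric(1))
    if (all(gains == -Inf)) break
    iBest <- which.max(gains)
    sp <- splits[[iBest]]
    g1 <- names(sp$s)[sp$s > 0]
    g2 <- names(sp$s)[sp$s < 0]
    newComms <- list(g1, g2)
    newSplits <- lapply(newComms, function(nodes)
      if (length(nodes) >= 2) leadingEigenBisect(g, nodes) else NULL)
    comms <- c(comms[-iBest], newComms)
    splits <- c(splits[-iBest], newSplits)
  }
  ## relabel by decreasing size, ties by smallest member name
  ord <- order(-vapply(comms, length, integer(1)),
               vapply(comms, function(x) sort(x)[1], character(1)))
  comms <- comms[ord]
  mem <- integer(numNodes(g))
  names(mem) <- nodeNames(g)
  for (ci in seq_along(comms)) mem[comms[[ci]]] <- ci - 1L
  Q <- modularityQ(g, mem)
  new("Partition", membership = mem, Q = Q)
}

#' @describeIn detectCommunities named 0-based membership vector.
#' @param p a `Partition`.
#' @export
communityMembership <- function(p) {
  stopifnot(is(p, "Partition"))
  p@membership
}

#' @describeIn detectCommunities number of communities K.
#' @export
numCommunities <- function(p) {
  stopifnot(is(p, "Partition"))
  if (!length(p@membership)) 0L else length(unique(p@membership))
}

#' @describeIn detectCommunities modularity Q of the partition.
#' @export
partitionQ <- function(p) {
  stopifnot(is(p, "Partition"))
  p@Q
}

setMethod("show", "Partition", function(object) {
  sizes <- sort(table(object@membership), decreasing = TRUE)
  cat(sprintf("Partition: %d nodes in %d communities (Q = %.4f)\n",
              length(object@membership), numCommunities(object), object@Q))
  cat("  sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
})

#' Construct a Partition from a membership vector
#'
#' @param membership named vector of community labels (coerced to 0-based
#'   consecutive integers by decreasing community size).
#' @param g optional [GeneGraph-class]; when given, `Q` is computed.
#' @return a [Partition-class].
#' @export
partition <- function(membership, g = NULL) {
  lab <- as.factor(membership)
  sizes <- table(lab)
  lev <- names(sort(sizes, decreasing = TRUE))
  mem <- setNames(match(as.character(lab), lev) - 1L, names(membership))
  Q <- if (is.null(g)) NA_real_ else modularityQ(g, mem)
  new("Partition", membership = mem, Q = if (is.na(Q)) 0 else Q)
}

#' Force genes into specific communities
#'
#' Applies a manual override table (columns `gene`, `forced_cluster`) to a
#' partition, the supported route for reproducing curated reassignments of
#' weakly-affiliated genes.
#'
#' @param p a [Partition-class].
#' @param override data.frame with columns `gene` and `forced_cluster`.
#' @param g optional [GeneGraph-class] to recompute Q.
#' @return a [Partition-class].
#' @export
applyClusterOverride <- function(p, override, g = NULL) {
  stopifnot(is(p, "Partition"), all(c("gene", "forced_cluster") %in% names(override)))
  mem <- p@membership
  unknown <- setdiff(override$gene, names(mem))
  if (length(unknown)) stop("unknown gene(s) in override: ", paste(unknown, collapse = ", "))
  mem[override$gene] <- as.integer(override$forced_cluster)
  Q <- if (is.null(g)) p@Q else modularityQ(g, mem)
  new("Partition", membership = mem, Q = Q)
}

#' Select per-community target genes by FCI
#'
#' For each community, picks the `nTargets` genes with the highest
#' composite FCI (ties broken lexicographically by gene id). Communities
#' smaller than `nTargets` contribute all their genes, with a warning.
#'
#' @param fr an [FCIResult-class] with computed scores.
#' @param p a [Partition-class] over the same genes.
#' @param nTargets targets per community (default 5).
#' @return named list (one element per community label, as character) of
#'   ordered gene vectors, highest FCI first.
#' @export
selectTargets <- function(fr, p, nTargets = 5) {
  stopifnot(is(fr, "FCIResult"), is(p, "Partition"))
  fci <- fciScores(fr)
  if (!setequal(names(fci), names(p@membership)))
    stop("FCI scores and partition must cover the same gene set")
  labs <- sort(unique(p@membership))
  out <- lapply(labs, function(lab) {
    genes <- names(p@membership)[p@membership == lab]
    if (length(genes) < nTargets)
      warning(sprintf("community %d has only %d gene(s) (< %d targets)",
                      lab, length(genes), nTargets))
    sc <- fci[genes]
    genes <- genes[order(-sc, genes)]
    head(genes, nTargets)
  })
  names(out) <- as.character(labs)
  out
}

#' Normalized mutual information between two labelings
#'
#' NMI with the `2 I(X;Y) / (H(X) + H(Y))` normalization, the standard
#' recovery score for planted-partition benchmarks. Returns 1 for
#' identical partitions (up to label renaming) and 0 for independent ones.
#'
#' @param a,b label vectors of equal length (names ignored; order aligned).
#' @return scalar in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 && hy == 0) return(1)
  if (hx == 0 || hy == 0) return(0)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
  2 * mi / (hx + hy)
}
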