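#' Construct a GeneGraph
#'
#' Builds the undirected simple gene network used by all topology and
#' message-passing code. Self-loops are dropped and duplicate edges
#' collapsed (with a message reporting how many), matching the convention
#' of removing self-loops before graph attention to prevent feature
#' oversmoothing.
#'
#' @param x an `igraph` object, a two-column character matrix/data.frame of
#'   edges, or a character vector of node names (for edgeless graphs, used
#'   only in degenerate tests).
#' @param nodes optional character vector of node names to include even if
#'   isolated.
#' @return a [GeneGraph-class] object.
#' @examples
#' g <- GeneGraph(cbind(c("a", "b"), c("b", "c")))
#' numNodes(g)
#' @export
GeneGraph <- function(x, nodes = NULL) {
  if (igraph::is_igraph(x)) {
    g <- x
    if (is.null(igraph::V(g)$name))
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  } else if (is.character(x) && is.null(dim(x))) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, length(x), name = x)
  } else {
    em <- as.matrix(x)
    if (ncol(em) < 2) stop("edge input must have two columns")
    em <- cbind(as.character(em[, 1]), as.character(em[, 2]))
    verts <- unique(c(em[, 1], em[, 2], nodes))
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    missing <- setdiff(verts, igraph::V(g)$name)
    if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  }
  nLoop <- sum(igraph::which_loop(g))
  nMulti <- sum(igraph::which_multiple(g))
  if (nLoop || nMulti)
    message(sprintf("dropped %d self-loop(s) and collapsed %d duplicate edge(s)",
                    nLoop, nMulti))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  new("GeneGraph", graph = g)
}

#' @describeIn GeneGraph number of nodes.
#' @param object,g a `GeneGraph`.
#' @export
numNodes <- function(g) igraph::vcount(g@graph)

#' @describeIn GeneGraph number of (undirected) edges.
#' @export
numEdges <- function(g) igraph::ecount(g@graph)

#' @describeIn GeneGraph node (gene) names.
#' @export
nodeNames <- function(g) igraph::V(g@graph)$name

#' @describeIn GeneGraph dense 0/1 adjacency matrix with named dimnames.
#' @export
adjacencyMatrix <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g@graph, sparse = TRUE))
  storage.mode(a) <- "double"
  a
}

#' @describeIn GeneGraph the underlying igraph object.
#' @export
asIgraph <- function(g) g@graph

setMethod("show", "GeneGraph", function(object) {
  cat(sprintf("GeneGraph with %d nodes and %d edges\n",
              numNodes(object), numEdges(object)))
  nm <- nodeNames(object)
  cat("  nodes:", paste(head(nm, 6), collapse = ", "),
      if (length(nm) > 6) "..." else "", "\n")
})

## Connectivity guard for distance-based metrics: errors with the component
## decomposition so the user can see what is disconnected.
.assertConnected <- function(g, what = "this operation") {
  comps <- igraph::components(g@graph)
  if (comps$no > 1) {
    sizes <- sort(comps$csize, decreasing = TRUE)
    stop(sprintf(
      "graph is disconnected (%d components of sizes %s); %s requires a connected graph",
      comps$no, paste(sizes, collapse = ", "), what))
  }
  invisible(TRUE)
}
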