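#' @import methods
#' @importFrom stats cor cor.test sd var rnorm runif rbinom quantile setNames
#' @importFrom stats ave uniroot
#' @importFrom utils read.table write.table head packageVersion
NULL

## Canonical metric order used throughout the package.
.METRICS <- c(
  "degree", "betweenness", "closeness", "clustering",
  "neighborhood_connectivity", "radiality", "eccentricity",
  "avg_shortest_path", "stress", "topological_coefficient"
)

## Path-length-like metrics whose standardized scores are sign-inverted by
## default so that a larger z always means "more central".
.INVERTED_DEFAULT <- c("avg_shortest_path", "eccentricity", "stress")

#' GeneGraph: an undirected, simple gene interaction network
#'
#' Thin S4 wrapper around an [igraph::igraph] object that enforces the
#' invariants every downstream computation relies on: the graph is
#' undirected, has no self-loops, no multi-edges, and carries unique
#' character node names (gene symbols).
#'
#' @slot graph an undirected simple `igraph` object with named vertices.
#'
#' @seealso [GeneGraph()], [computeCentralities()], [detectCommunities()]
#' @exportClass GeneGraph
setClass("GeneGraph", representation(graph = "ANY"))

setValidity("GeneGraph", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("slot 'graph' must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (any(igraph::which_loop(g))) return("graph must not contain self-loops")
  if (any(igraph::which_multiple(g))) return("graph must not contain duplicate edges")
  nm <- igraph::V(g)$name
  if (is.null(nm) || anyNA(nm)) return("all nodes must be named")
  if (anyDuplicated(nm)) return("node names must be unique")
  TRUE
})

#' CentralityTable: ten raw topological metrics per node
#'
#' One row per gene, one column per metric, in the canonical order
#' degree, betweenness, closeness, clustering, neighborhood_connectivity,
#' radiality, eccentricity, avg_shortest_path, stress,
#' topological_coefficient. Betweenness and stress are unnormalized counts
#' over unordered source-target pairs.
#'
#' @slot metrics numeric matrix, rownames are node names, colnames the
#'   canonical metric names.
#'
#' @seealso [computeCentralities()], [standardizeMetrics()]
#' @exportClass CentralityTable
setClass("CentralityTable", representation(metrics = "matrix"))

setValidity("CentralityTable", function(object) {
  m <- object@metrics
  if (!is.numeric(m)) return("metrics must be numeric")
  if (is.null(rownames(m))) return("metrics must have node rownames")
  if (!identical(colnames(m), .METRICS))
    return("metric columns must be the ten canonical metrics in order")
  if (any(!is.finite(m))) return("all metric values must be finite")
  TRUE
})

#' FCIWeights: per-metric weights and the inverted-metric set
#'
#' Nonnegative weight per metric with positive total, plus the subset of
#' metrics whose z-scores are multiplied by -1 before fusion (the
#' path-length-like metrics where smaller raw values mean more central).
#'
#' @slot weights named nonnegative numeric vector covering all ten metrics.
#' @slot inverted character subset of metric names.
#'
#' @seealso [fciWeights()], [computeFCI()]
#' @exportClass FCIWeights
setClass("FCIWeights", representation(weights = "numeric", inverted = "character"))

setValidity("FCIWeights", function(object) {
  w <- object@weights
  if (!identical(sort(names(w)), sort(.METRICS)))
    return("weights must name exactly the ten canonical metrics")
  if (any(w < 0) || anyNA(w)) return("weights must be nonnegative")
  if (sum(w) <= 0) return("total weight W must be positive")
  if (!all(object@inverted %in% .METRICS))
    return("inverted set must be a subset of the canonical metrics")
  TRUE
})

#' FCIResult: standardized metric scores and the composite index
#'
#' @slot zscores numeric matrix of per-metric z-scores (post inversion),
#'   same shape as the source [CentralityTable].
#' @slot fci named numeric vector, the per-node Functional Centrality Index.
#' @slot weights the [FCIWeights] used.
#'
#' @seealso [standardizeMetrics()], [computeFCI()], [selectTargets()]
#' @exportClass FCIResult
setClass("FCIResult", representation(
  zscores = "matrix", fci = "numeric", weights = "FCIWeights"
))

setValidity("FCIResult", function(object) {
  if (!identical(colnames(object@zscores), .METRICS))
    return("zscore columns must be the ten canonical metrics in order")
  if (length(object@fci) > 0 &&
      !identical(names(object@fci), rownames(object@zscores)))
    return("fci names must match zscore rownames")
  if (any(!is.finite(object@zscores))) return("z-scores must be finite")
  TRUE
})

#' Partition: node-to-community assignment with its modularity
#'
#' Community labels are consecutive integers `0..K-1`, relabeled by
#' decreasing community size.
#'
#' @slot membership named integer vector of community labels (0-based).
#' @slot Q modularity of the partition on the graph it was computed from.
#'
#' @seealso [detectCommunities()], [modularityQ()], [selectTargets()]
#' @exportClass Partition
setClass("Partition", representation(membership = "integer", Q = "numeric"))

setValidity("Partition", function(object) {
  m <- object@membership
  if (is.null(names(m)) || anyDuplicated(names(m)))
    return("membership must be named with unique node names")
  if (length(m) && (anyNA(m) || min(m) < 0))
    return("labels must be nonnegative integers")
  if (length(object@Q) != 1 || is.na(object@Q) ||
      object@Q < -1 - 1e-9 || object@Q > 1 + 1e-9)
    return("Q must be a single value in [-1, 1]")
  TRUE
})

#' DrugLibrary: dual molecular representation of a compound library
#'
#' Binary substructure fingerprints plus a physicochemical descriptor
#' matrix, with the fitted column-wise standardization (z-score) moments.
#'
#' @slot drugIds character vector of unique compound identifiers.
#' @slot fingerprints numeric 0/1 matrix, drugs x fingerprint bits.
#' @slot descriptors numeric matrix, drugs x descriptors (raw).
#' @slot descriptorsStd numeric matrix of column z-scores of `descriptors`.
#' @slot scaler list with `mu` and `sigma` (column moments) or empty list
#'   when no scaler has been fitted.
#' @slot rejects character vector of input identifiers that failed
#'   featurization (e.g. unparsable SMILES).
#'
#' @seealso [featurizeLibrary()], [drugLibrary()], [fitScaler()]
#' @exportClass DrugLibrary
setClass("DrugLibrary", representation(
  drugIds = "character", fingerprints = "matrix", descriptors = "matrix",
  descriptorsStd = "matrix", scaler = "list", rejects = "character"
))

setValidity("DrugLibrary", function(object) {
  n <- length(object@drugIds)
  if (anyDuplicated(object@drugIds)) return("drug ids must be unique")
  if (nrow(object@fingerprints) != n || nrow(object@descriptors) != n)
    return("feature matrices must have one row per drug")
  fp <- object@fingerprints
  if (length(fp) && !all(fp %in% c(0, 1))) return("fingerprints must be binary")
  if (length(object@descriptorsStd) && any(!is.finite(object@descriptorsStd)))
    return("standardized descriptors must be finite")
  TRUE
})

#' DTIModel: the multi-modal drug-gene interaction scorer
#'
#' Holds the full parameter set of the network (molecular encoder,
#' cluster-aware gene encoder, dual cross-attention, score and uncertainty
#' heads, auxiliary gene-classification head and molecular decoders),
#' together with its configuration, the gene universe, the graph edges and
#' the cluster one-hot matrix it was built for.
#'
#' @slot params named list of parameter matrices/vectors.
#' @slot config model configuration as produced by [dtiModelConfig()].
#' @slot genes character vector of gene names (row order of embeddings).
#' @slot edges integer matrix of directed edge endpoints (both directions
#'   of every undirected edge), used by the graph-attention layers.
#' @slot clusterOneHot numeric genes x K one-hot cluster membership matrix.
#' @slot meta list of training metadata (history, best epoch, seed, ...).
#'
#' @seealso [initDTIModel()], [trainDTIModel()], [predictMC()]
#' @exportClass DTIModel
setClass("DTIModel", representation(
  params = "list", config = "list", genes = "character",
  edges = "matrix", clusterOneHot = "matrix", meta = "list"
))

setValidity("DTIModel", function(object) {
  if (nrow(object@clusterOneHot) != length(object@genes))
    return("cluster one-hot must have one row per gene")
  TRUE
})
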