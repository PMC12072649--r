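#' Per-metric weights for the Functional Centrality Index
#'
#' The index is a weighted mean of z-standardized metrics. Betweenness
#' defaults to weight 2 (it is deliberately up-weighted as the main carrier
#' of information-flow importance) and every other metric to 1. Metrics
#' where a *smaller* raw value means a more central node — average shortest
#' path length, eccentricity and stress — are sign-inverted after
#' standardization so that larger z uniformly means more central. All of
#' this is configurable.
#'
#' @param weights named numeric vector of nonnegative weights; metrics not
#'   named keep their default.
#' @param inverted character vector of metrics to sign-invert.
#' @return an [FCIWeights-class] object.
#' @examples
#' fciWeights()                      # defaults
#' fciWeights(c(closeness = 3))      # up-weight closeness
#' @export
fciWeights <- function(weights = NULL, inverted = .INVERTED_DEFAULT) {
  w <- setNames(rep(1, length(.METRICS)), .METRICS)
  w["betweenness"] <- 2
  if (!is.null(weights)) {
    bad <- setdiff(names(weights), .METRICS)
    if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
    w[names(weights)] <- weights
  }
  new("FCIWeights", weights = w, inverted = inverted)
}

setMethod("show", "FCIWeights", function(object) {
  cat("FCIWeights (W =", sum(object@weights), ")\n")
  print(object@weights)
  cat("inverted:", paste(object@inverted, collapse = ", "), "\n")
})

#' Standardize centrality metrics to z-scores
#'
#' Each metric column is centered by its mean and divided by its sample
#' standard deviation, so nonconstant columns have mean 0 and variance 1
#' across nodes. Columns in the inverted set are then multiplied by -1.
#' A metric with zero variance carries no ranking information; its z-scores
#' are set to 0 and a warning is emitted.
#'
#' @param ct a [CentralityTable-class] with at least 2 nodes.
#' @param weights an [FCIWeights-class] (supplies the inverted set).
#' @return an [FCIResult-class] with the z-score matrix filled in and an
#'   empty `fci` slot (see [computeFCI()]).
#' @export
standardizeMetrics <- function(ct, weights = fciWeights()) {
  stopifnot(is(ct, "CentralityTable"), is(weights, "FCIWeights"))
  m <- ct@metrics
  if (nrow(m) < 2) stop("standardization requires at least 2 nodes")
  mu <- colMeans(m)
  sigma <- apply(m, 2, sd)
  z <- sweep(m, 2, mu, "-")
  constant <- sigma < .Machine$double.eps * 100
  if (any(constant)) {
    warning("zero-variance metric(s) set to z = 0: ",
            paste(colnames(m)[constant], collapse = ", "))
    sigma[constant] <- 1
  }
  z <- sweep(z, 2, sigma, "/")
  z[, constant] <- 0
  inv <- intersect(weights@inverted, colnames(z))
  z[, inv] <- -z[, inv]
  new("FCIResult", zscores = z, fci = numeric(0), weights = weights)
}

#' Compute the Functional Centrality Index
#'
#' Fuses the standardized metrics into the composite per-node score
#' `FCI_i = (1/W) * sum_m w_m * z_{m,i}` with `W = sum_m w_m`. The index is
#' invariant under positive rescaling of the weight vector.
#'
#' @param x an [FCIResult-class] (from [standardizeMetrics()]) or a
#'   [CentralityTable-class] (standardized internally).
#' @param weights an [FCIWeights-class].
#' @return an [FCIResult-class] with the `fci` slot populated.
#' @examples
#' g <- GeneGraph(igraph::make_star(6, mode = "undirected"))
#' fci <- computeFCI(computeCentralities(g))
#' head(sort(fciScores(fci), decreasing = TRUE))
#' @export
computeFCI <- function(x, weights = fciWeights()) {
  if (is(x, "CentralityTable")) x <- standardizeMetrics(x, weights)
  stopifnot(is(x, "FCIResult"))
  w <- weights@weights[colnames(x@zscores)]
  W <- sum(w)
  if (W <= 0) stop("total weight W must be positive")
  fci <- as.numeric(x@zscores %*% w) / W
  names(fci) <- rownames(x@zscores)
  new("FCIResult", zscores = x@zscores, fci = fci, weights = weights)
}

#' @describeIn computeFCI the named per-node FCI vector.
#' @param fr an `FCIResult`.
#' @export
fciScores <- function(fr) {
  stopifnot(is(fr, "FCIResult"))
  fr@fci
}

#' @describeIn computeFCI the per-metric z-score matrix.
#' @export
fciZscores <- function(fr) {
  stopifnot(is(fr, "FCIResult"))
  fr@zscores
}

setMethod("show", "FCIResult", function(object) {
  cat(sprintf("FCIResult: %d nodes\n", nrow(object@zscores)))
  if (length(object@fci)) {
    top <- head(sort(object@fci, decreasing = TRUE), 5)
    cat("top FCI:\n")
    print(round(top, 4))
  } else cat("(z-scores only; run computeFCI() for the composite index)\n")
})

#' Correlate the FCI with each raw centrality metric
#'
#' Pearson correlation (with a two-sided test) of the composite index
#' against each of the raw metrics, the standard companion report showing
#' which facets of topology the fused index tracks most closely.
#'
#' @param fr an [FCIResult-class] with computed scores.
#' @param ct the [CentralityTable-class] the index was built from.
#' @return data.frame with columns `metric`, `r`, `p`; `r` is `NA` for
#'   constant metrics (correlation undefined).
#' @export
correlateFCI <- function(fr, ct) {
  stopifnot(is(fr, "FCIResult"), is(ct, "CentralityTable"))
  fci <- fciScores(fr)
  if (!length(fci)) stop("FCIResult has no computed scores")
  m <- ct@metrics[names(fci), , drop = FALSE]
  if (length(fci) < 3) stop("correlation requires at least 3 nodes")
  res <- lapply(colnames(m), function(cn) {
    x <- m[, cn]
    if (sd(x) < .Machine$double.eps * 100 || sd(fci) == 0)
      return(data.frame(metric = cn, r = NA_real_, p = NA_real_))
     t <- cor.test(fci, x, method = "pearson", alternative = "two.sided")
    data.frame(metric = cn, r = unname(t$estimate), p = t$p.value)
  })
  do.call(rbind, res)
}
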