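#' Configuration of the synthetic benchmark generator
#'
#' The generator emulates the statistical structure the screening
#' framework assumes: a gene network with planted community structure
#' (stochastic block model), drugs whose fingerprints and descriptors are
#' informative of a latent pharmacological factor, and interaction labels
#' drawn from a logistic model on the drug-gene latent alignment with a
#' calibrated 10% positive rate. A planted multi-target drug is aligned
#' with two cluster centroids simultaneously.
#'
#' Defaults define the benchmark conditions: 100 genes in K = 5 planted
#' clusters with within/between edge probabilities 0.3/0.02, 200 drugs,
#' 10% positive interactions.
#'
#' @param nGenes number of genes (>= 3 K).
#' @param K planted cluster count.
#' @param pIn,pOut within/between-cluster edge probabilities.
#' @param nDrugs library size.
#' @param latentDim latent pharmacology dimension.
#' @param positiveRate target interaction positive rate.
#' @param noiseSd descriptor noise standard deviation.
#' @param nBits synthetic fingerprint width.
#' @param nDesc synthetic descriptor width.
#' @param alpha logistic slope on the drug-gene latent inner product (the
#'   single knob controlling task difficulty/separability).
#' @param geneNoise latent noise around a gene's cluster centroid.
#' @param drugNoise latent noise around an aligned drug's home centroid.
#' @param alignedFrac fraction of drugs aligned to a cluster centroid
#'   (the rest are isotropic background compounds of reduced latent
#'   norm).
#' @param pairsPerDrug genes sampled per drug when building the labeled
#'   interaction table.
#' @return named list of settings (class `"syntheticConfig"`).
#' @export
syntheticConfig <- function(nGenes = 100, K = 5, pIn = 0.3, pOut = 0.02,
                            nDrugs = 200, latentDim = 8,
                            positiveRate = 0.10, noiseSd = 0.1,
                            nBits = 128, nDesc = 16, alpha = 12,
                            geneNoise = 0.3, drugNoise = 0.5,
                            alignedFrac = 0.25, pairsPerDrug = 40) {
  stopifnot(pOut >= 0, pOut < pIn, pIn <= 1,
            positiveRate > 0, positiveRate < 1, nGenes >= 3 * K)
  cfg <- list(nGenes = nGenes, K = K, pIn = pIn, pOut = pOut,
              nDrugs = nDrugs, latentDim = latentDim,
              positiveRate = positiveRate, noiseSd = noiseSd,
              nBits = nBits, nDesc = nDesc, alpha = alpha,
              geneNoise = geneNoise, drugNoise = drugNoise,
              alignedFrac = alignedFrac, pairsPerDrug = pairsPerDrug)
  class(cfg) <- c("syntheticConfig", "list")
  cfg
}

.unitRows <- function(X) X / pmax(sqrt(rowSums(X^2)), 1e-12)

## K approximately orthogonal unit centroids in latentDim dimensions.
.clusterCentroids <- function(K, latentDim) {
  M <- matrix(rnorm(latentDim * max(K, latentDim)), ncol = latentDim)
  Q <- qr.Q(qr(t(M)))[, seq_len(K), drop = FALSE]
  t(Q)
}

#' Generate a planted-community gene network
#'
#' Samples a stochastic-block-model graph at the configured block sizes
#' and edge probabilities, keeps the largest connected component, and
#' returns the surviving true labels. Sampling is retried (up to 10
#' attempts) until the retained component covers at least 90% of the
#' genes; otherwise an error is raised.
#'
#' @param config a [syntheticConfig()].
#' @param seed RNG seed.
#' @return list with `graph` (a [GeneGraph-class]), `truePartition` (a
#'   [Partition-class] of the planted labels) and `latents` (gene latent
#'   matrix, rows named by gene).
#' @export
generateNetwork <- function(config = syntheticConfig(), seed = 1L) {
  set.seed(seed)
  K <- config$K
  sizes <- diff(round(seq(0, config$nGenes, length.out = K + 1)))
  pm <- matrix(config$pOut, K, K)
  diag(pm) <- config$pIn
  for (attempt in 1:10) {
    ig <- igraph::sample_sbm(config$nGenes, pref.matrix = pm,
                             block.sizes = sizes, directed = FALSE)
    igraph::V(ig)$name <- sprintf("g%03d", seq_len(config$nGenes))
    labels <- rep(seq_len(K) - 1L, sizes)
    comp <- igraph::components(ig)
    keep <- comp$membership == which.max(comp$csize)
    if (sum(keep) >= 0.9 * config$nGenes) {
      sub <- igraph::induced_subgraph(ig, which(keep))
      g <- GeneGraph(sub)
      mem <- setNames(labels[keep], igraph::V(ig)$name[keep])
      mem <- mem[nodeNames(g)]
      part <- new("Partition", membership = mem, Q = modularityQ(g, mem))
      cent <- .clusterCentroids(K, config$latentDim)
      lat <- .unitRows(cent[mem + 1L, , drop = FALSE] +
                         config$geneNoise * matrix(rnorm(length(mem) * config$latentDim),
                                                   ncol = config$latentDim))
      rownames(lat) <- names(mem)
      return(list(graph = g, truePartition = part, latents = lat,
                  centroids = cent))
    }
  }
  stop("could not sample a sufficiently connected planted-partition graph in 10 attempts")
}

#' Generate a synthetic drug library
#'
#' Each drug carries a latent pharmacology vector: an `alignedFrac`
#' fraction of drugs sit near a (randomly chosen) cluster centroid while
#' the rest are isotropic background compounds with reduced latent norm.
#' One planted multi-target drug (`id "D_MT"`) is aligned with two
#' cluster centroids at once. Fingerprint bits are Bernoulli draws whose
#' probabilities are logistic in the latent; descriptors are a linear map
#' of the latent plus Gaussian noise — so the observable features are
#' informative of the latent, as real fingerprints and descriptors are of
#' pharmacology.
#'
#' @param config a [syntheticConfig()].
#' @param centroids K x latentDim cluster centroid matrix (from
#'   [generateNetwork()]).
#' @param seed RNG seed.
#' @return list with `lib` (a [DrugLibrary-class]), `latents` (drug
#'   latent matrix), `homeCluster` (0-based or NA for background drugs)
#'   and `multiTargetDrug` (id) with `multiTargetClusters` (0-based pair).
#' @export
generateDrugs <- function(config = syntheticConfig(), centroids, seed = 1L) {
  set.seed(seed + 1000L)
  n <- config$nDrugs
  ld <- config$latentDim
  ids <- sprintf("D%04d", seq_len(n))
  nAligned <- max(1L, round(config$alignedFrac * n))
  home <- rep(NA_integer_, n)
  home[seq_len(nAligned)] <- sample(config$K, nAligned, replace = TRUE) - 1L
  lat <- matrix(rnorm(n * ld), ncol = ld)
  lat <- 0.6 * .unitRows(lat)  # background: reduced latent norm
  al <- which(!is.na(home))
  lat[al, ] <- .unitRows(centroids[home[al] + 1L, , drop = FALSE] +
                           config$drugNoise * matrix(rnorm(length(al) * ld), ncol = ld))
  ## planted multi-target drug aligned with clusters 0 and 1
  mtClusters <- c(0L, 1L)
  mtIdx <- n
  ids[mtIdx] <- "D_MT"
  home[mtIdx] <- NA_integer_
  lat[mtIdx, ] <- as.numeric(.unitRows(matrix(colSums(centroids[mtClusters + 1L, , drop = FALSE]),
                                              nrow = 1)))
  Wf <- matrix(rnorm(ld * config$nBits), ld, config$nBits)
  probs <- .sigmoid(2 * (lat %*% Wf))
  fp <- matrix(rbinom(length(probs), 1, probs), nrow = n)
  Wd <- matrix(rnorm(ld * config$nDesc), ld, config$nDesc)
  de <- lat %*% Wd + config$noiseSd * matrix(rnorm(n * config$nDesc), ncol = config$nDesc)
  lib <- drugLibrary(ids, fp, de)
  rownames(lat) <- ids
  list(lib = lib, latents = lat, homeCluster = setNames(home, ids),
       multiTargetDrug = "D_MT", multiTargetClusters = mtClusters)
}

#' Generate labeled drug-gene interactions
#'
#' Samples `pairsPerDrug` genes per drug and draws labels from
#' `Bernoulli(sigmoid(alpha * <drug latent, gene latent> + beta))`, with
#' the intercept `beta` calibrated by root finding so the expected
#' positive rate matches the configured rate (an error is raised if the
#' realized rate misses it by more than 20%). Pairs with the planted
#' multi-target drug are always included for the genes of its two
#' clusters' top alignment. Gene disease labels mark membership of the
#' designated disease cluster (cluster 0).
#'
#' @param drugs output of [generateDrugs()].
#' @param genes output of [generateNetwork()].
#' @param config a [syntheticConfig()].
#' @param seed RNG seed.
#' @return list with `interactions` (data.frame `drug_id`, `gene_id`,
#'   `label`, `trueProb`), `geneLabels` (named 0/1), and `beta`.
#' @export
generateInteractions <- function(drugs, genes, config = syntheticConfig(),
                                 seed = 1L) {
  set.seed(seed + 2000L)
  dl <- drugs$latents
  gl <- genes$latents
  geneNames <- rownames(gl)
  nG <- length(geneNames)
  ppd <- min(config$pairsPerDrug, nG)
  pairD <- rep(rownames(dl), each = ppd)
  pairG <- as.character(unlist(lapply(seq_len(nrow(dl)), function(i)
    sample(geneNames, ppd))))
  dots <- rowSums(dl[pairD, , drop = FALSE] * gl[pairG, , drop = FALSE])
  rate <- function(beta) mean(.sigmoid(config$alpha * dots + beta))
  beta <- tryCatch(
    uniroot(function(b) rate(b) - config$positiveRate, c(-30, 30))$root,
    error = function(e) stop("intercept calibration failed: ", conditionMessage(e)))
  p <- .sigmoid(config$alpha * dots + beta)
  y <- rbinom(length(p), 1, p)
  achieved <- mean(y)
  if (abs(achieved - config$positiveRate) > 0.2 * config$positiveRate +
      2 * sqrt(config$positiveRate / length(y)))
    stop(sprintf("calibration missed the positive rate (%.3f vs %.3f)",
                 achieved, config$positiveRate))
  interactions <- data.frame(drug_id = pairD, gene_id = pairG, label = y,
                             trueProb = p, stringsAsFactors = FALSE)
  ## drop accidental duplicate pairs from the per-drug gene sampling
  interactions <- interactions[!duplicated(interactions[c("drug_id", "gene_id")]), ]
  mem <- genes$truePartition@membership
  geneLabels <- setNames(as.integer(mem[geneNames] == 0L), geneNames)
  list(interactions = interactions, geneLabels = geneLabels, beta = beta)
}

#' Generate the full synthetic benchmark
#'
#' Convenience wrapper chaining [generateNetwork()], [generateDrugs()]
#' and [generateInteractions()] under one seed.
#'
#' @param config a [syntheticConfig()].
#' @param seed RNG seed.
#' @return list with `graph`, `truePartition`, `geneLatents`, `lib`,
#'   `drugLatents`, `interactions`, `geneLabels`, `multiTargetDrug`,
#'   `multiTargetClusters`, `beta`.
#' @export
generateBenchmark <- function(config = syntheticConfig(), seed = 1L) {
  net <- generateNetwork(config, seed)
  drugs <- generateDrugs(config, net$centroids, seed)
  inter <- generateInteractions(drugs, net, config, seed)
  list(graph = net$graph, truePartition = net$truePartition,
       geneLatents = net$latents, lib = drugs$lib,
       drugLatents = drugs$latents, interactions = inter$interactions,
       geneLabels = inter$geneLabels,
       multiTargetDrug = drugs$multiTargetDrug,
       multiTargetClusters = drugs$multiTargetClusters, beta = inter$beta)
}
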