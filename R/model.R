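#' Configuration of the multi-modal interaction model
#'
#' Architecture hyperparameters of the drug-gene scorer. Defaults follow
#' the reference architecture: 512-dimensional drug and gene embeddings,
#' two graph-attention layers with 8 heads each (concatenation
#' aggregation) plus a global transformer-attention layer, 8-head
#' cross-attention with head dimension `dModel/8` (64 at default, giving
#' scale 1/8), dropout 0.2 (0.1 on attention weights), a 3-layer scorer
#' (`2d -> d -> d/2 -> 1`), an identically shaped aleatoric-uncertainty
#' head whose sigmoid output is scaled by 0.5 (ceiling 0.5), and 10
#' Monte-Carlo dropout passes at inference.
#'
#' @param dModel embedding width for both drugs and genes (default 512).
#' @param heads attention heads for the GAT, transformer and
#'   cross-attention blocks; must divide `dModel`.
#' @param dropout dropout probability in encoders and heads.
#' @param attnDropout dropout probability on attention weights.
#' @param leakySlope negative slope of the leaky-rectifier activation.
#' @param uncertaintyScale multiplier of the uncertainty head output.
#' @param uncertaintyActivation `"sigmoid"` (bounded, default) or
#'   `"softplus"`.
#' @param mcPasses Monte-Carlo dropout passes `T`.
#' @param reconVariant reconstruction-loss variant, `"bce_mse"` (default)
#'   or `"eq_l1_l2"` (L1 on fingerprints + squared L2 on descriptors).
#' @return named list of settings (class `"dtiModelConfig"`).
#' @export
dtiModelConfig <- function(dModel = 512, heads = 8, dropout = 0.2,
                           attnDropout = 0.1, leakySlope = 0.2,
                           uncertaintyScale = 0.5,
                           uncertaintyActivation = c("sigmoid", "softplus"),
                           mcPasses = 10,
                           reconVariant = c("bce_mse", "eq_l1_l2")) {
  if (dModel %% heads != 0) stop("heads must divide dModel")
  cfg <- list(
    dModel = dModel, heads = heads, dk = dModel / heads,
    attnScale = 1 / sqrt(dModel / heads),
    dropout = dropout, attnDropout = attnDropout, leakySlope = leakySlope,
    uncertaintyScale = uncertaintyScale,
    uncertaintyActivation = match.arg(uncertaintyActivation),
    mcPasses = mcPasses, reconVariant = match.arg(reconVariant),
    nGatLayers = 2
  )
  class(cfg) <- c("dtiModelConfig", "list")
  cfg
}

#' Initialize a DTIModel
#'
#' Builds the full parameter set with Xavier-uniform initialization: the
#' two-pathway molecular encoder, the learnable gene embedding matrix, two
#' graph-attention layers plus the global transformer layer, the
#' cluster-aware projection (`dModel + K -> dModel`), dual cross-attention,
#' score/uncertainty heads, the gene-classification head and the molecular
#' decoders used by the autoencoding objective.
#'
#' @param graph a connected [GeneGraph-class].
#' @param partitionObj a [Partition-class] labeling every gene of `graph`.
#' @param nBits fingerprint width the model expects.
#' @param nDesc descriptor width the model expects.
#' @param config a [dtiModelConfig()].
#' @param seed integer seed for the initialization RNG.
#' @return a [DTIModel-class].
#' @export
initDTIModel <- function(graph, partitionObj, nBits, nDesc,
                         config = dtiModelConfig(), seed = 1L) {
  stopifnot(is(graph, "GeneGraph"), is(partitionObj, "Partition"))
  genes <- nodeNames(graph)
  mem <- partitionObj@membership
  if (!all(genes %in% names(mem)))
    stop("gene(s) absent from the partition: ",
         paste(head(setdiff(genes, names(mem)), 5), collapse = ", "))
  K <- max(mem) + 1L
  C <- matrix(0, length(genes), K, dimnames = list(genes, NULL))
  C[cbind(seq_along(genes), mem[genes] + 1L)] <- 1
  el <- igraph::as_edgelist(graph@graph, names = FALSE)
  edges <- rbind(el, el[, 2:1, drop = FALSE])  # both directions
  storage.mode(edges) <- "integer"

  d <- config$dModel
  h <- d                       # encoder hidden width
  d2 <- max(2L, d %/% 2L)      # scorer mid width
  M <- length(genes)
  set.seed(seed)
  p <- list()
  ## molecular encoder: fingerprint and descriptor pathways, then fusion
  p$fp1.W <- .xavier(nBits, h); p$fp1.b <- numeric(h)
  p$fp2.W <- .xavier(h, h);     p$fp2.b <- numeric(h)
  p$fpLN.g <- rep(1, h);        p$fpLN.b <- numeric(h)
  p$de1.W <- .xavier(nDesc, h); p$de1.b <- numeric(h)
  p$de2.W <- .xavier(h, h);     p$de2.b <- numeric(h)
  p$deLN.g <- rep(1, h);        p$deLN.b <- numeric(h)
  p$mol.W <- .xavier(2 * h, d); p$mol.b <- numeric(d)
  p$molLN.g <- rep(1, d);       p$molLN.b <- numeric(d)
  ## gene encoder
  p$E <- .xavier(M, d)
  dh <- d / config$heads
  p$gat1.W <- .xavier(d, d)
  p$gat1.aSrc <- .xavier(2 * dh, 1, nrow = config$heads, ncol = dh)
  p$gat1.aDst <- .xavier(2 * dh, 1, nrow = config$heads, ncol = dh)
  p$gat2.W <- .xavier(d, d)
  p$gat2.aSrc <- .xavier(2 * dh, 1, nrow = config$heads, ncol = dh)
  p$gat2.aDst <- .xavier(2 * dh, 1, nrow = config$heads, ncol = dh)
  p$gat2p.W <- .xavier(d, d); p$gat2p.b <- numeric(d)
  p$tr.Wq <- .xavier(d, d); p$tr.Wk <- .xavier(d, d); p$tr.Wv <- .xavier(d, d)
  p$clus.W <- .xavier(d + K, d); p$clus.b <- numeric(d)
  p$clusLN.g <- rep(1, d); p$clusLN.b <- numeric(d)
  ## dual cross-attention
  p$ca.dWq <- .xavier(d, d); p$ca.dWk <- .xavier(d, d); p$ca.dWv <- .xavier(d, d)
  p$ca.gWq <- .xavier(d, d); p$ca.gWk <- .xavier(d, d); p$ca.gWv <- .xavier(d, d)
  ## score and uncertainty heads (2d -> d -> d/2 -> 1)
  for (pre in c("sc", "un")) {
    p[[paste0(pre, "1.W")]] <- .xavier(2 * d, d)
    p[[paste0(pre, "1.b")]] <- numeric(d)
    p[[paste0(pre, "LN1.g")]] <- rep(1, d); p[[paste0(pre, "LN1.b")]] <- numeric(d)
    p[[paste0(pre, "2.W")]] <- .xavier(d, d2)
    p[[paste0(pre, "2.b")]] <- numeric(d2)
    p[[paste0(pre, "LN2.g")]] <- rep(1, d2); p[[paste0(pre, "LN2.b")]] <- numeric(d2)
    p[[paste0(pre, "3.W")]] <- .xavier(d2, 1)
    p[[paste0(pre, "3.b")]] <- numeric(1)
  }
  ## gene-classification head (d -> d/2 -> 1)
  p$gh1.W <- .xavier(d, d2); p$gh1.b <- numeric(d2)
  p$gh2.W <- .xavier(d2, 1); p$gh2.b <- numeric(1)
  ## molecular decoders (d -> h -> width)
  p$decFp1.W <- .xavier(d, h); p$decFp1.b <- numeric(h)
  p$decFp2.W <- .xavier(h, nBits); p$decFp2.b <- numeric(nBits)
  p$decDe1.W <- .xavier(d, h); p$decDe1.b <- numeric(h)
  p$decDe2.W <- .xavier(h, nDesc); p$decDe2.b <- numeric(nDesc)

  cfg <- unclass(config)
  cfg$K <- K; cfg$nBits <- nBits; cfg$nDesc <- nDesc
  new("DTIModel", params = p, config = cfg, genes = genes, edges = edges,
      clusterOneHot = C, meta = list(seed = seed))
}

setMethod("show", "DTIModel", function(object) {
  cfg <- object@config
  nPar <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf("DTIModel: %d genes, K = %d clusters, dModel = %d, %d heads, %s parameters\n",
              length(object@genes), cfg$K, cfg$dModel, cfg$heads,
              format(nPar, big.mark = ",")))
  if (!is.null(object@meta$history))
    cat(sprintf("  trained %d epoch(s); best val AUROC %.3f\n",
                nrow(object@meta$history), object@meta$bestValAUROC))
})

## ---------------------------------------------------------------------------
## Forward building blocks. Each returns out + cache.

.molPathFwd <- function(X, pfx, p, cfg, train) {
  l1 <- .nnLinearFwd(X, p[[paste0(pfx, "1.W")]], p[[paste0(pfx, "1.b")]])
  a1 <- .nnLeakyFwd(l1$out, cfg$leakySlope)
  d1 <- .nnDropoutFwd(a1$out, cfg$dropout, train)
  l2 <- .nnLinearFwd(d1$out, p[[paste0(pfx, "2.W")]], p[[paste0(pfx, "2.b")]])
  a2 <- .nnLeakyFwd(l2$out, cfg$leakySlope)
  d2 <- .nnDropoutFwd(a2$out, cfg$dropout, train)
  ln <- .nnLayerNormFwd(d2$out, p[[paste0(pfx, "LN.g")]], p[[paste0(pfx, "LN.b")]])
  list(out = ln$out, l1 = l1, a1 = a1, d1 = d1, l2 = l2, a2 = a2, d2 = d2, ln = ln)
}

.molPathBwd <- function(dOut, cache, pfx, grads) {
  lb <- .nnLayerNormBwd(dOut, cache$ln)
  grads[[paste0(pfx, "LN.g")]] <- grads[[paste0(pfx, "LN.g")]] + lb$dg
  grads[[paste0(pfx, "LN.b")]] <- grads[[paste0(pfx, "LN.b")]] + lb$db
  dx <- .nnDropoutBwd(lb$dX, cache$d2)
  dx <- .nnLeakyBwd(dx, cache$a2)
  g2 <- .nnLinearBwd(dx, cache$l2)
  grads[[paste0(pfx, "2.W")]] <- grads[[paste0(pfx, "2.W")]] + g2$dW
  grads[[paste0(pfx, "2.b")]] <- grads[[paste0(pfx, "2.b")]] + g2$db
  dx <- .nnDropoutBwd(g2$dX, cache$d1)
  dx <- .nnLeakyBwd(dx, cache$a1)
  g1 <- .nnLinearBwd(dx, cache$l1)
  grads[[paste0(pfx, "1.W")]] <- grads[[paste0(pfx, "1.W")]] + g1$dW
  grads[[paste0(pfx, "1.b")]] <- grads[[paste0(pfx, "1.b")]] + g1$db
  list(grads = grads, dX = g1$dX)
}

#' Encode drug molecules
#'
#' Fingerprint and descriptor features each pass a two-layer perceptron
#' (leaky rectifier, dropout, layer normalization); the two pathway
#' outputs are concatenated and projected to the shared `dModel`-wide
#' molecular embedding space.
#'
#' @param model a [DTIModel-class].
#' @param fingerprints binary matrix, batch x `nBits`.
#' @param descriptors standardized descriptor matrix, batch x `nDesc`.
#' @param train logical; keep dropout active (stochastic forward)?
#' @return list with `hmol` (batch x dModel embedding matrix) and `cache`.
#' @export
encodeMolecules <- function(model, fingerprints, descriptors, train = FALSE) {
  cfg <- model@config
  p <- model@params
  if (ncol(fingerprints) != cfg$nBits || ncol(descriptors) != cfg$nDesc)
    stop(sprintf("feature widths (%d, %d) do not match model config (%d, %d)",
                 ncol(fingerprints), ncol(descriptors), cfg$nBits, cfg$nDesc))
  fp <- .molPathFwd(fingerprints, "fp", p, cfg, train)
  de <- .molPathFwd(descriptors, "de", p, cfg, train)
  cat2 <- cbind(fp$out, de$out)
  proj <- .nnLinearFwd(cat2, p$mol.W, p$mol.b)
  ln <- .nnLayerNormFwd(proj$out, p$molLN.g, p$molLN.b)
  list(hmol = ln$out, cache = list(fp = fp, de = de, proj = proj, ln = ln,
                                   h = ncol(fp$out)))
}

.encodeMoleculesBwd <- function(dH, cache, grads) {
  lb <- .nnLayerNormBwd(dH, cache$ln)
  grads$molLN.g <- grads$molLN.g + lb$dg
  grads$molLN.b <- grads$molLN.b + lb$db
  gp <- .nnLinearBwd(lb$dX, cache$proj)
  grads$mol.W <- grads$mol.W + gp$dW
  grads$mol.b <- grads$mol.b + gp$db
  h <- cache$h
  r1 <- .molPathBwd(gp$dX[, 1:h, drop = FALSE], cache$fp, "fp", grads)
  r2 <- .molPathBwd(gp$dX[, (h + 1):(2 * h), drop = FALSE], cache$de, "de", r1$grads)
  r2$grads
}

#' Encode genes with the cluster-aware graph network
#'
#' The learnable gene embeddings pass two multi-head graph-attention
#' layers (per-neighborhood softmax attention, concatenation aggregation,
#' width-restoring linear map after the second layer), then a global
#' multi-head self-attention (transformer) layer over the whole gene set.
#' The cluster one-hot vector is concatenated and projected back to
#' `dModel` with layer normalization and dropout.
#'
#' @inheritParams encodeMolecules
#' @return list with `z` (genes x dModel matrix, rownames = genes) and
#'   `cache`.
#' @export
encodeGenes <- function(model, train = FALSE) {
  cfg <- model@config
  p <- model@params
  g1 <- .nnGatFwd(p$E, p$gat1.W, p$gat1.aSrc, p$gat1.aDst, model@edges,
                  cfg$heads, cfg$leakySlope)
  a1 <- .nnLeakyFwd(g1$out, cfg$leakySlope)
  g2 <- .nnGatFwd(a1$out, p$gat2.W, p$gat2.aSrc, p$gat2.aDst, model@edges,
                  cfg$heads, cfg$leakySlope)
  a2 <- .nnLeakyFwd(g2$out, cfg$leakySlope)
  wr <- .nnLinearFwd(a2$out, p$gat2p.W, p$gat2p.b)
  tr <- .nnSelfAttnFwd(wr$out, p$tr.Wq, p$tr.Wk, p$tr.Wv, cfg$heads,
                       cfg$attnDropout, train)
  catC <- cbind(tr$out, model@clusterOneHot)
  pr <- .nnLinearFwd(catC, p$clus.W, p$clus.b)
  ln <- .nnLayerNormFwd(pr$out, p$clusLN.g, p$clusLN.b)
  dp <- .nnDropoutFwd(ln$out, cfg$dropout, train)
  z <- dp$out
  rownames(z) <- model@genes
  list(z = z, cache = list(g1 = g1, a1 = a1, g2 = g2, a2 = a2, wr = wr,
                           tr = tr, pr = pr, ln = ln, dp = dp,
                           d = cfg$dModel))
}

.encodeGenesBwd <- function(dZ, cache, grads) {
  dx <- .nnDropoutBwd(dZ, cache$dp)
  lb <- .nnLayerNormBwd(dx, cache$ln)
  grads$clusLN.g <- grads$clusLN.g + lb$dg
  grads$clusLN.b <- grads$clusLN.b + lb$db
  gp <- .nnLinearBwd(lb$dX, cache$pr)
  grads$clus.W <- grads$clus.W + gp$dW
  grads$clus.b <- grads$clus.b + gp$db
  dTr <- gp$dX[, 1:cache$d, drop = FALSE]  # cluster one-hot is constant
  tb <- .nnSelfAttnBwd(dTr, cache$tr)
  grads$tr.Wq <- grads$tr.Wq + tb$dWq
  grads$tr.Wk <- grads$tr.Wk + tb$dWk
  grads$tr.Wv <- grads$tr.Wv + tb$dWv
  gw <- .nnLinearBwd(tb$dX, cache$wr)
  grads$gat2p.W <- grads$gat2p.W + gw$dW
  grads$gat2p.b <- grads$gat2p.b + gw$db
  dx <- .nnLeakyBwd(gw$dX, cache$a2)
  g2b <- .nnGatBwd(dx, cache$g2)
  grads$gat2.W <- grads$gat2.W + g2b$dW
  grads$gat2.aSrc <- grads$gat2.aSrc + g2b$daSrc
  grads$gat2.aDst <- grads$gat2.aDst + g2b$daDst
  dx <- .nnLeakyBwd(g2b$dH, cache$a1)
  g1b <- .nnGatBwd(dx, cache$g1)
  grads$gat1.W <- grads$gat1.W + g1b$dW
  grads$gat1.aSrc <- grads$gat1.aSrc + g1b$daSrc
  grads$gat1.aDst <- grads$gat1.aDst + g1b$daDst
  grads$E <- grads$E + g1b$dH
  grads
}

#' Fuse a drug and a gene embedding by dual cross-attention
#'
#' Queries from the drug attend over the gene representation and vice
#' versa. Each `dModel` embedding is treated as `heads` tokens of the head
#' dimension (`dk = dModel/heads`, scale `1/sqrt(dk)` = 1/8 at defaults),
#' so each direction yields a heads x heads attention map whose rows are
#' probability distributions. The two attended vectors are concatenated
#' into the fused pair representation of width `2 * dModel`.
#'
#' @inheritParams encodeMolecules
#' @param hmol drug embeddings (batch x dModel).
#' @param z gene embeddings aligned row-wise with `hmol`.
#' @return list with `fused`, attention map lists `attnDG`, `attnGD`, and
#'   `cache`.
#' @export
crossAttend <- function(model, hmol, z, train = FALSE) {
  cfg <- model@config
  if (ncol(hmol) != cfg$dModel || ncol(z) != cfg$dModel)
    stop("embedding widths do not match model config")
  prm <- list(dWq = model@params$ca.dWq, dWk = model@params$ca.dWk,
              dWv = model@params$ca.dWv, gWq = model@params$ca.gWq,
              gWk = model@params$ca.gWk, gWv = model@params$ca.gWv)
  .nnCrossAttnFwd(hmol, z, prm, cfg$heads, cfg$attnDropout, train)
}

.crossAttendBwd <- function(dFused, cache, grads) {
  cb <- .nnCrossAttnBwd(dFused, cache)
  grads$ca.dWq <- grads$ca.dWq + cb$grads$dWq
  grads$ca.dWk <- grads$ca.dWk + cb$grads$dWk
  grads$ca.dWv <- grads$ca.dWv + cb$grads$dWv
  grads$ca.gWq <- grads$ca.gWq + cb$grads$gWq
  grads$ca.gWk <- grads$ca.gWk + cb$grads$gWk
  grads$ca.gWv <- grads$ca.gWv + cb$grads$gWv
  list(grads = grads, dHm = cb$dHm, dZ = cb$dZ)
}

.headFwd <- function(X, pre, p, cfg, train) {
  l1 <- .nnLinearFwd(X, p[[paste0(pre, "1.W")]], p[[paste0(pre, "1.b")]])
  a1 <- .nnLeakyFwd(l1$out, cfg$leakySlope)
  n1 <- .nnLayerNormFwd(a1$out, p[[paste0(pre, "LN1.g")]], p[[paste0(pre, "LN1.b")]])
  d1 <- .nnDropoutFwd(n1$out, cfg$dropout, train)
  l2 <- .nnLinearFwd(d1$out, p[[paste0(pre, "2.W")]], p[[paste0(pre, "2.b")]])
  a2 <- .nnLeakyFwd(l2$out, cfg$leakySlope)
  n2 <- .nnLayerNormFwd(a2$out, p[[paste0(pre, "LN2.g")]], p[[paste0(pre, "LN2.b")]])
  d2 <- .nnDropoutFwd(n2$out, cfg$dropout, train)
  l3 <- .nnLinearFwd(d2$out, p[[paste0(pre, "3.W")]], p[[paste0(pre, "3.b")]])
  list(logits = as.numeric(l3$out),
       cache = list(l1 = l1, a1 = a1, n1 = n1, d1 = d1, l2 = l2, a2 = a2,
                    n2 = n2, d2 = d2, l3 = l3))
}

.headBwd <- function(dLogits, cache, pre, grads) {
  g3 <- .nnLinearBwd(matrix(dLogits, ncol = 1), cache$l3)
  grads[[paste0(pre, "3.W")]] <- grads[[paste0(pre, "3.W")]] + g3$dW
  grads[[paste0(pre, "3.b")]] <- grads[[paste0(pre, "3.b")]] + g3$db
  dx <- .nnDropoutBwd(g3$dX, cache$d2)
  n2 <- .nnLayerNormBwd(dx, cache$n2)
  grads[[paste0(pre, "LN2.g")]] <- grads[[paste0(pre, "LN2.g")]] + n2$dg
  grads[[paste0(pre, "LN2.b")]] <- grads[[paste0(pre, "LN2.b")]] + n2$db
  dx <- .nnLeakyBwd(n2$dX, cache$a2)
  g2 <- .nnLinearBwd(dx, cache$l2)
  grads[[paste0(pre, "2.W")]] <- grads[[paste0(pre, "2.W")]] + g2$dW
  grads[[paste0(pre, "2.b")]] <- grads[[paste0(pre, "2.b")]] + g2$db
  dx <- .nnDropoutBwd(g2$dX, cache$d1)
  n1 <- .nnLayerNormBwd(dx, cache$n1)
  grads[[paste0(pre, "LN1.g")]] <- grads[[paste0(pre, "LN1.g")]] + n1$dg
  grads[[paste0(pre, "LN1.b")]] <- grads[[paste0(pre, "LN1.b")]] + n1$db
  dx <- .nnLeakyBwd(n1$dX, cache$a1)
  g1 <- .nnLinearBwd(dx, cache$l1)
  grads[[paste0(pre, "1.W")]] <- grads[[paste0(pre, "1.W")]] + g1$dW
  grads[[paste0(pre, "1.b")]] <- grads[[paste0(pre, "1.b")]] + g1$db
  list(grads = grads, dX = g1$dX)
}

#' Score a fused pair representation
#'
#' The interaction score is `sigmoid` of the 3-layer scorer output
#' (`s` in `[0, 1]`); the aleatoric uncertainty head has the same shape
#' and ends, by default, in a sigmoid scaled by `uncertaintyScale` so
#' `u` is bounded in `[0, 0.5]` (a softplus variant is configurable).
#'
#' @inheritParams encodeMolecules
#' @param fused fused pair matrix (batch x `2*dModel`).
#' @return list with `s`, `u`, the raw logits, and `cache`.
#' @export
scoreInteraction <- function(model, fused, train = FALSE) {
  cfg <- model@config
  if (ncol(fused) != 2 * cfg$dModel)
    stop("fused width must be 2 * dModel")
  sc <- .headFwd(fused, "sc", model@params, cfg, train)
  un <- .headFwd(fused, "un", model@params, cfg, train)
  s <- .sigmoid(sc$logits)
  u <- if (cfg$uncertaintyActivation == "sigmoid")
    cfg$uncertaintyScale * .sigmoid(un$logits)
  else cfg$uncertaintyScale * .softplus(un$logits)
  list(s = s, u = u, sLogits = sc$logits, uLogits = un$logits,
       cache = list(sc = sc$cache, un = un$cache))
}

## ---------------------------------------------------------------------------
## Whole-network forward over a batch of (drug, gene) pairs.
.forwardPairs <- function(model, fingerprints, descriptors, geneIdx, train) {
  enc <- encodeMolecules(model, fingerprints, descriptors, train)
  gen <- encodeGenes(model, train)
  z <- gen$z[geneIdx, , drop = FALSE]
  ca <- crossAttend(model, enc$hmol, z, train)
  so <- scoreInteraction(model, ca$fused, train)
  list(s = so$s, u = so$u, sLogits = so$sLogits, uLogits = so$uLogits,
       hmol = enc$hmol, zAll = gen$z, fused = ca$fused,
       attnDG = ca$attnDG, attnGD = ca$attnGD,
       cache = list(enc = enc$cache, gen = gen$cache, ca = ca, so = so$cache,
                    geneIdx = geneIdx))
}

#' Monte-Carlo-dropout prediction for drug-gene pairs
#'
#' Runs `T` stochastic forward passes with all dropout layers active and
#' returns, per pair, the mean interaction score, the population variance
#' over the passes (epistemic uncertainty), and the mean aleatoric
#' uncertainty emitted by the dedicated head.
#'
#' @param model a trained [DTIModel-class].
#' @param fingerprints,descriptors drug feature matrices, one row per pair.
#' @param genes character vector of gene names, one per pair.
#' @param T number of stochastic passes (default from the model config).
#' @param seed RNG seed making the passes reproducible.
#' @return data.frame with columns `gene_id`, `sbar`, `sigma2`, `u`.
#' @export
predictMC <- function(model, fingerprints, descriptors, genes,
                      T = model@config$mcPasses, seed = 1L) {
  if (T < 1) stop("T must be >= 1")
  idx <- match(genes, model@genes)
  if (anyNA(idx)) stop("unknown gene(s): ",
                       paste(unique(genes[is.na(idx)]), collapse = ", "))
  set.seed(seed)
  S <- matrix(0, nrow(fingerprints), T)
  U <- matrix(0, nrow(fingerprints), T)
  for (t in seq_len(T)) {
    fw <- .forwardPairs(model, fingerprints, descriptors, idx, train = TRUE)
    S[, t] <- fw$s
    U[, t] <- fw$u
  }
  sbar <- rowMeans(S)
  sigma2 <- rowMeans((S - sbar)^2)
  data.frame(gene_id = genes, sbar = sbar, sigma2 = sigma2,
             u = rowMeans(U), stringsAsFactors = FALSE)
}

#' Deterministic (evaluation-mode) pair prediction
#'
#' @inheritParams predictMC
#' @return data.frame with columns `gene_id`, `s`, `u`.
#' @export
predictPairs <- function(model, fingerprints, descriptors, genes) {
  idx <- match(genes, model@genes)
  if (anyNA(idx)) stop("unknown gene(s): ",
                       paste(unique(genes[is.na(idx)]), collapse = ", "))
  fw <- .forwardPairs(model, fingerprints, descriptors, idx, train = FALSE)
  data.frame(gene_id = genes, s = fw$s, u = fw$u, stringsAsFactors = FALSE)
}

## Zero-filled gradient container matching the parameter list.
.zeroGrads <- function(params) {
  lapply(params, function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  })
}
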