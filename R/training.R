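#' Training hyperparameters
#'
#' Defaults follow the reference protocol: Adam (beta1 = 0.9,
#' beta2 = 0.999) with learning rate 1e-4, batch size 64, L2 weight decay
#' 1e-5, early stopping on validation AUROC with patience 10 epochs, an
#' uncertainty regularization weight of 0.1, unit weights on the gene and
#' reconstruction objectives, and a self-supervised molecular pretraining
#' phase weighted 0.3.
#'
#' @param learningRate Adam step size.
#' @param batchSize minibatch size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param weightDecay L2 penalty coefficient.
#' @param patience early-stopping patience (epochs without validation
#'   AUROC improvement).
#' @param maxEpochs maximum training epochs.
#' @param lambdaU uncertainty-regularization weight in the interaction
#'   loss.
#' @param lambdaG gene-classification loss weight.
#' @param lambdaR molecular-reconstruction loss weight.
#' @param lambdaPretrain reconstruction weight during the pretraining
#'   phase.
#' @param pretrainEpochs epochs of molecular-autoencoder warm-up on the
#'   drug library before joint training (0 disables).
#' @param seed RNG seed for shuffling, dropout and initialization order.
#' @return named list of settings (class `"dtiTrainConfig"`).
#' @export
dtiTrainConfig <- function(learningRate = 1e-4, batchSize = 64,
                           beta1 = 0.9, beta2 = 0.999, weightDecay = 1e-5,
                           patience = 10, maxEpochs = 50, lambdaU = 0.1,
                           lambdaG = 1.0, lambdaR = 1.0,
                           lambdaPretrain = 0.3, pretrainEpochs = 0,
                           seed = 1L) {
  stopifnot(patience >= 1, lambdaU >= 0, lambdaG >= 0, lambdaR >= 0)
  cfg <- list(learningRate = learningRate, batchSize = batchSize,
              beta1 = beta1, beta2 = beta2, weightDecay = weightDecay,
              patience = patience, maxEpochs = maxEpochs, lambdaU = lambdaU,
              lambdaG = lambdaG, lambdaR = lambdaR,
              lambdaPretrain = lambdaPretrain,
              pretrainEpochs = pretrainEpochs, seed = as.integer(seed))
  class(cfg) <- c("dtiTrainConfig", "list")
  cfg
}

#' Split an interaction dataset into train/validation/test
#'
#' Label-stratified random split at the pair level: within each label
#' class the requested fractions are honored exactly (largest-remainder
#' apportionment), so the positive rate of every split stays within
#' rounding of the global rate. Reproducible given `seed`.
#'
#' @param interactions data.frame with columns `drug_id`, `gene_id`,
#'   `label` (0/1).
#' @param fractions train/validation/test fractions (positive, sum 1).
#' @param seed RNG seed.
#' @return the input data.frame with a `split` column
#'   (`"train"`/`"val"`/`"test"`).
#' @export
splitDataset <- function(interactions, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-9,
            all(c("drug_id", "gene_id", "label") %in% names(interactions)))
  if (anyDuplicated(interactions[c("drug_id", "gene_id")]))
    stop("duplicate (drug, gene) pairs in the interaction table")
  set.seed(seed)
  tags <- c("train", "val", "test")
  split <- character(nrow(interactions))
  for (lab in unique(interactions$label)) {
    idx <- which(interactions$label == lab)
    idx <- sample(idx)
    n <- length(idx)
    bounds <- diff(c(0, round(cumsum(fractions) * n)))
    split[idx] <- rep(tags, bounds)
  }
  if (any(!tags %in% split))
    stop("a split would be empty; enlarge the dataset or the fractions")
  interactions$split <- split
  interactions
}

#' Interaction loss with aleatoric uncertainty weighting
#'
#' `L = sum BCE(s, y) / u + lambdaU * sum log(u)`: confident (small `u`)
#' errors are amplified while the log term penalizes blanket
#' overestimation of uncertainty. `u` is clamped at 1e-6.
#'
#' @param s predicted scores in `[0, 1]`.
#' @param y binary labels.
#' @param u aleatoric uncertainties (positive).
#' @param lambdaU regularization weight.
#' @param reduction `"sum"` (the printed form) or `"mean"`.
#' @return scalar loss.
#' @export
lossDti <- function(s, y, u, lambdaU = 0.1, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (anyNA(s) || anyNA(y) || anyNA(u)) stop("NaN/NA in loss inputs")
  u <- pmax(u, 1e-6)
  sc <- pmin(pmax(s, 1e-12), 1 - 1e-12)
  bce <- -(y * log(sc) + (1 - y) * log(1 - sc))
  tot <- sum(bce / u) + lambdaU * sum(log(u))
  if (reduction == "mean") tot / length(s) else tot
}

#' Gene-classification loss
#'
#' Weighted binary cross-entropy of the disease-gene head probabilities:
#' `lambdaG * sum BCE(p_j, y_j)`.
#'
#' @param p predicted gene probabilities in `[0, 1]`.
#' @param y binary gene labels.
#' @param lambdaG loss weight.
#' @param reduction `"sum"` or `"mean"`.
#' @return scalar loss.
#' @export
lossGene <- function(p, y, lambdaG = 1.0, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (length(p) != length(y)) stop("one label per gene is required")
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  bce <- -(y * log(pc) + (1 - y) * log(1 - pc))
  lambdaG * (if (reduction == "mean") mean(bce) else sum(bce))
}

#' Molecular reconstruction loss
#'
#' Default variant `"bce_mse"`: elementwise-mean binary cross-entropy
#' between the sigmoid fingerprint reconstruction and the input bits,
#' plus elementwise-mean squared error on the standardized descriptors.
#' Variant `"eq_l1_l2"` uses the L1 norm of the raw fingerprint residual
#' plus the squared L2 norm of the descriptor residual.
#'
#' @param fpHat fingerprint reconstruction (probabilities for
#'   `"bce_mse"`, raw values for `"eq_l1_l2"`).
#' @param f observed fingerprint bits.
#' @param dHat descriptor reconstruction.
#' @param d observed standardized descriptors.
#' @param lambdaR loss weight.
#' @param variant `"bce_mse"` or `"eq_l1_l2"`.
#' @return scalar loss.
#' @export
lossRecon <- function(fpHat, f, dHat, d, lambdaR = 1.0,
                      variant = c("bce_mse", "eq_l1_l2")) {
  variant <- match.arg(variant)
  if (length(fpHat) != length(f) || length(dHat) != length(d))
    stop("decoder output widths do not match the feature widths")
  if (variant == "bce_mse") {
    pc <- pmin(pmax(fpHat, 1e-12), 1 - 1e-12)
    bce <- mean(-(f * log(pc) + (1 - f) * log(1 - pc)))
    lambdaR * (bce + mean((dHat - d)^2))
  } else {
    lambdaR * (sum(abs(fpHat - f)) + sum((dHat - d)^2))
  }
}

#' Classification metrics for interaction predictions
#'
#' AUROC is computed by the rank statistic (Mann-Whitney, ties averaged);
#' precision, recall and F1 use the 0.5 decision threshold. With a
#' single-class input AUROC is `NA`.
#'
#' @param scores predicted scores.
#' @param labels binary labels.
#' @param threshold decision threshold (default 0.5).
#' @return named list: `auroc`, `precision`, `recall`, `f1`.
#' @export
evaluateScores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  auroc <- if (!any(pos) || all(pos)) NA_real_ else {
    r <- rank(scores)
    n1 <- sum(pos); n0 <- sum(!pos)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  pred <- scores >= threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos); fn <- sum(!pred & pos)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(auroc = auroc, precision = precision, recall = recall, f1 = f1)
}

## ---------------------------------------------------------------------------
## Decoder forward/backward (molecular autoencoding heads).

.decoderFwd <- function(hmol, p, cfg) {
  f1 <- .nnLinearFwd(hmol, p$decFp1.W, p$decFp1.b)
  fa <- .nnLeakyFwd(f1$out, cfg$leakySlope)
  f2 <- .nnLinearFwd(fa$out, p$decFp2.W, p$decFp2.b)
  d1 <- .nnLinearFwd(hmol, p$decDe1.W, p$decDe1.b)
  da <- .nnLeakyFwd(d1$out, cfg$leakySlope)
  d2 <- .nnLinearFwd(da$out, p$decDe2.W, p$decDe2.b)
  list(fpLogits = f2$out, deOut = d2$out,
       cache = list(f1 = f1, fa = fa, f2 = f2, d1 = d1, da = da, d2 = d2))
}

.decoderBwd <- function(dFpLogits, dDeOut, cache, grads) {
  g2 <- .nnLinearBwd(dFpLogits, cache$f2)
  grads$decFp2.W <- grads$decFp2.W + g2$dW
  grads$decFp2.b <- grads$decFp2.b + g2$db
  dx <- .nnLeakyBwd(g2$dX, cache$fa)
  g1 <- .nnLinearBwd(dx, cache$f1)
  grads$decFp1.W <- grads$decFp1.W + g1$dW
  grads$decFp1.b <- grads$decFp1.b + g1$db
  dHm <- g1$dX
  g2 <- .nnLinearBwd(dDeOut, cache$d2)
  grads$decDe2.W <- grads$decDe2.W + g2$dW
  grads$decDe2.b <- grads$decDe2.b + g2$db
  dx <- .nnLeakyBwd(g2$dX, cache$da)
  g1 <- .nnLinearBwd(dx, cache$d1)
  grads$decDe1.W <- grads$decDe1.W + g1$dW
  grads$decDe1.b <- grads$decDe1.b + g1$db
  list(grads = grads, dHm = dHm + g1$dX)
}

## Gene-classification head forward/backward over all gene embeddings.
.geneHeadFwd <- function(z, p, cfg) {
  l1 <- .nnLinearFwd(z, p$gh1.W, p$gh1.b)
  a1 <- .nnLeakyFwd(l1$out, cfg$leakySlope)
  l2 <- .nnLinearFwd(a1$out, p$gh2.W, p$gh2.b)
  list(logits = as.numeric(l2$out), cache = list(l1 = l1, a1 = a1, l2 = l2))
}

.geneHeadBwd <- function(dLogits, cache, grads) {
  g2 <- .nnLinearBwd(matrix(dLogits, ncol = 1), cache$l2)
  grads$gh2.W <- grads$gh2.W + g2$dW
  grads$gh2.b <- grads$gh2.b + g2$db
  dx <- .nnLeakyBwd(g2$dX, cache$a1)
  g1 <- .nnLinearBwd(dx, cache$l1)
  grads$gh1.W <- grads$gh1.W + g1$dW
  grads$gh1.b <- grads$gh1.b + g1$db
  list(grads = grads, dZ = g1$dX)
}

## ---------------------------------------------------------------------------
## One joint forward + backward over a minibatch of pairs. Returns the
## (mean-reduced) total loss and the full gradient list.
.batchGrads <- function(model, fpX, deX, geneIdx, y, geneLabels, tcfg) {
  cfg <- model@config
  p <- model@params
  B <- length(y)
  fw <- .forwardPairs(model, fpX, deX, geneIdx, train = TRUE)
  dec <- .decoderFwd(fw$hmol, p, cfg)
  gh <- .geneHeadFwd(fw$zAll, p, cfg)
  gp <- .sigmoid(gh$logits)

  u <- pmax(fw$u, 1e-6)
  sc <- pmin(pmax(fw$s, 1e-12), 1 - 1e-12)
  bce <- -(y * log(sc) + (1 - y) * log(1 - sc))
  lDti <- (sum(bce / u) + tcfg$lambdaU * sum(log(u))) / B
  lGene <- lossGene(gp, geneLabels, tcfg$lambdaG, reduction = "mean")
  fpP <- .sigmoid(dec$fpLogits)
  lRecon <- if (cfg$reconVariant == "bce_mse")
    lossRecon(fpP, fpX, dec$deOut, deX, tcfg$lambdaR, "bce_mse")
  else lossRecon(dec$fpLogits, fpX, dec$deOut, deX, tcfg$lambdaR, "eq_l1_l2")
  loss <- lDti + lGene + lRecon

  grads <- .zeroGrads(p)
  ## interaction loss -> score/uncertainty logits (mean reduction)
  dSLogit <- (fw$s - y) / u / B
  dU <- (-bce / u^2 + tcfg$lambdaU / u) / B
  dU[fw$u < 1e-6] <- 0
  dULogit <- if (cfg$uncertaintyActivation == "sigmoid") {
    sig <- fw$u / cfg$uncertaintyScale
    dU * cfg$uncertaintyScale * sig * (1 - sig)
  } else dU * cfg$uncertaintyScale * .sigmoid(fw$uLogits)
  hb1 <- .headBwd(dSLogit, fw$cache$so$sc, "sc", grads)
  hb2 <- .headBwd(dULogit, fw$cache$so$un, "un", hb1$grads)
  dFused <- hb1$dX + hb2$dX
  cb <- .crossAttendBwd(dFused, fw$cache$ca, hb2$grads)
  grads <- cb$grads
  dHm <- cb$dHm

  ## reconstruction loss -> decoders and molecular embedding
  nf <- length(fpX); nd <- length(deX)
  if (cfg$reconVariant == "bce_mse") {
    dFpLogits <- tcfg$lambdaR * (fpP - fpX) / nf
    dDeOut <- tcfg$lambdaR * 2 * (dec$deOut - deX) / nd
  } else {
    dFpLogits <- tcfg$lambdaR * sign(dec$fpLogits - fpX)
    dDeOut <- tcfg$lambdaR * 2 * (dec$deOut - deX)
  }
  db <- .decoderBwd(dFpLogits, dDeOut, dec$cache, grads)
  grads <- db$grads
  dHm <- dHm + db$dHm
  grads <- .encodeMoleculesBwd(dHm, fw$cache$enc, grads)

  ## gene loss -> gene head; pair gradients scatter onto gene embeddings
  dGhLogit <- tcfg$lambdaG * (gp - geneLabels) / length(geneLabels)
  gb <- .geneHeadBwd(dGhLogit, gh$cache, grads)
  grads <- gb$grads
  dZAll <- gb$dZ
  agg <- rowsum(cb$dZ, geneIdx)
  dZAll[as.integer(rownames(agg)), ] <- dZAll[as.integer(rownames(agg)), ] + agg
  grads <- .encodeGenesBwd(dZAll, fw$cache$gen, grads)

  list(loss = loss, lDti = lDti, lGene = lGene, lRecon = lRecon,
       grads = grads)
}

## Adam update (in place on the params list); returns updated state.
.adamStep <- function(params, grads, state, tcfg) {
  t <- state$t + 1
  lr <- tcfg$learningRate
  b1 <- tcfg$beta1; b2 <- tcfg$beta2
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  for (nm in names(params)) {
    g <- grads[[nm]] + tcfg$weightDecay * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
  }
  state$t <- t
  state$params <- params
  state
}

#' Train the multi-modal interaction model
#'
#' Minimizes the composite objective (uncertainty-weighted interaction
#' loss + gene-classification loss + molecular reconstruction loss) with
#' Adam, monitoring AUROC on the validation split and early-stopping with
#' the configured patience; the returned model carries the
#' best-validation parameters. An optional self-supervised pretraining
#' phase first optimizes the reconstruction loss alone (weighted
#' `lambdaPretrain`) over the drug library.
#'
#' @param model an initialized [DTIModel-class].
#' @param lib a [DrugLibrary-class] providing the drug features.
#' @param interactions data.frame with `drug_id`, `gene_id`, `label` and a
#'   `split` column (see [splitDataset()]).
#' @param geneLabels named 0/1 vector over the model's genes
#'   (disease-gene head targets).
#' @param config a [dtiTrainConfig()].
#' @param verbose print per-epoch progress?
#' @return the trained [DTIModel-class]; `meta` holds the per-epoch
#'   `history` (epoch, loss terms, validation AUROC), `bestEpoch` and
#'   `bestValAUROC`.
#' @export
trainDTIModel <- function(model, lib, interactions, geneLabels,
                          config = dtiTrainConfig(), verbose = FALSE) {
  stopifnot(is(model, "DTIModel"), is(lib, "DrugLibrary"))
  if (!"split" %in% names(interactions))
    stop("interactions must carry a 'split' column; see splitDataset()")
  if (!all(model@genes %in% names(geneLabels)))
    stop("geneLabels must cover every model gene")
  gl <- as.numeric(geneLabels[model@genes])
  tr <- interactions[interactions$split == "train", ]
  va <- interactions[interactions$split == "val", ]
  if (sum(tr$label == 1) == 0) stop("no positive labels in the train split")
  dIdx <- function(d) {
    i <- match(d, lib@drugIds)
    if (anyNA(i)) stop("drug(s) missing from the library")
    i
  }
  trDrug <- dIdx(tr$drug_id); vaDrug <- dIdx(va$drug_id)
  trGene <- match(tr$gene_id, model@genes)
  vaGene <- match(va$gene_id, model@genes)
  if (anyNA(trGene) || anyNA(vaGene)) stop("gene(s) missing from the model")
  FP <- lib@fingerprints; DE <- lib@descriptorsStd

  set.seed(config$seed)
  state <- list(t = 0, m = .zeroGrads(model@params),
                v = .zeroGrads(model@params), params = model@params)

  ## optional molecular-autoencoder warm-up on the whole library
  if (config$pretrainEpochs > 0) {
    nD <- nrow(FP)
    for (ep in seq_len(config$pretrainEpochs)) {
      ord <- sample(nD)
      for (bi in split(ord, ceiling(seq_along(ord) / config$batchSize))) {
        model@params <- state$params
        grads <- .zeroGrads(model@params)
        enc <- encodeMolecules(model, FP[bi, , drop = FALSE],
                               DE[bi, , drop = FALSE], train = TRUE)
        dec <- .decoderFwd(enc$hmol, model@params, model@config)
        fpP <- .sigmoid(dec$fpLogits)
        w <- config$lambdaPretrain
        dFpLogits <- w * (fpP - FP[bi, , drop = FALSE]) / length(fpP)
        dDeOut <- w * 2 * (dec$deOut - DE[bi, , drop = FALSE]) / length(dec$deOut)
        db <- .decoderBwd(dFpLogits, dDeOut, dec$cache, grads)
        grads <- .encodeMoleculesBwd(db$dHm, enc$cache, db$grads)
        state <- .adamStep(model@params, grads, state, config)
      }
    }
  }

  history <- data.frame()
  best <- list(auroc = -Inf, epoch = 0, params = state$params)
  nTr <- nrow(tr)
  for (ep in seq_len(config$maxEpochs)) {
    ord <- sample(nTr)
    epLoss <- 0
    for (bi in split(ord, ceiling(seq_along(ord) / config$batchSize))) {
      model@params <- state$params
      bg <- .batchGrads(model, FP[trDrug[bi], , drop = FALSE],
                        DE[trDrug[bi], , drop = FALSE], trGene[bi],
                        tr$label[bi], gl, config)
      state <- .adamStep(model@params, bg$grads, state, config)
      epLoss <- epLoss + bg$loss * length(bi)
    }
    epLoss <- epLoss / nTr
    model@params <- state$params
    fwVal <- .forwardPairs(model, FP[vaDrug, , drop = FALSE],
                           DE[vaDrug, , drop = FALSE], vaGene, train = FALSE)
    valAuroc <- evaluateScores(fwVal$s, va$label)$auroc
    history <- rbind(history, data.frame(epoch = ep, loss = epLoss,
                                         valAUROC = valAuroc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val AUROC %.4f", ep, epLoss, valAuroc))
    if (!is.na(valAuroc) && valAuroc > best$auroc) {
      best <- list(auroc = valAuroc, epoch = ep, params = state$params)
    } else if (ep - best$epoch >= config$patience) break
  }
  model@params <- best$params
  model@meta <- c(model@meta[setdiff(names(model@meta), c("history", "bestEpoch", "bestValAUROC"))],
                  list(history = history, bestEpoch = best$epoch,
                       bestValAUROC = best$auroc, trainConfig = config))
  model
}

#' Evaluate a trained model on one split
#'
#' Deterministic (evaluation-mode) forward over the requested split,
#' scored with [evaluateScores()].
#'
#' @inheritParams trainDTIModel
#' @param split which split tag to evaluate (default `"test"`).
#' @return named list: `auroc`, `precision`, `recall`, `f1`, `n`.
#' @export
evaluateModel <- function(model, lib, interactions, split = "test") {
  te <- interactions[interactions$split == split, ]
  if (!nrow(te)) stop("split '", split, "' is empty")
  idx <- match(te$drug_id, lib@drugIds)
  gIdx <- match(te$gene_id, model@genes)
  fw <- .forwardPairs(model, lib@fingerprints[idx, , drop = FALSE],
                      lib@descriptorsStd[idx, , drop = FALSE], gIdx,
                      train = FALSE)
  c(evaluateScores(fw$s, te$label), list(n = nrow(te)))
}
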