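## Neural-network primitives: each layer has a forward returning (out,
## cache) and a backward mapping (dOut, cache) to input/parameter
## gradients. All tensors are plain matrices, batch rows x features.
## Analytic gradients are verified against finite differences in the test
## suite.

.nnLinearFwd <- function(X, W, b) {
  out <- X %*% W
  out <- sweep(out, 2, b, "+")
  list(out = out, X = X, W = W)
}

.nnLinearBwd <- function(dOut, cache) {
  list(dX = tcrossprod(dOut, cache$W),
       dW = crossprod(cache$X, dOut),
       db = colSums(dOut))
}

.nnLeakyFwd <- function(X, slope = 0.2) {
  neg <- X < 0
  out <- X
  out[neg] <- slope * X[neg]
  list(out = out, neg = neg, slope = slope)
}

.nnLeakyBwd <- function(dOut, cache) {
  dOut[cache$neg] <- cache$slope * dOut[cache$neg]
  dOut
}

## Inverted dropout; in eval mode the layer is the identity.
.nnDropoutFwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, mask = NULL))
  mask <- matrix((runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(out = X * mask, mask = mask)
}

.nnDropoutBwd <- function(dOut, cache) {
  if (is.null(cache$mask)) dOut else dOut * cache$mask
}

## Row-wise layer normalization with learned gain/bias per feature.
.nnLayerNormFwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(xhat, 2, g, "*")
  out <- sweep(out, 2, b, "+")
  list(out = out, xhat = xhat, inv = inv, g = g)
}

.nnLayerNormBwd <- function(dOut, cache) {
  xhat <- cache$xhat
  dg <- colSums(dOut * xhat)
  db <- colSums(dOut)
  dxhat <- sweep(dOut, 2, cache$g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dX = dX, dg = dg, db = db)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

.rowSoftmax <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / .rowSums(E, nrow(E), ncol(E))
}

## ---------------------------------------------------------------------------
## Graph attention layer (multi-head, concatenation aggregation).
## edges: 2-column integer matrix of directed (src, dst) pairs; for an
## undirected graph both orientations are present. Each destination node
## attends over its neighbors with a per-edge softmax.

.nnGatFwd <- function(H, W, aSrc, aDst, edges, heads, slope = 0.2) {
  M <- nrow(H)
  dh <- ncol(W) / heads
  P <- H %*% W
  src <- edges[, 1]
  dst <- edges[, 2]
  out <- matrix(0, M, ncol(W))
  hc <- vector("list", heads)
  for (k in seq_len(heads)) {
    cols <- ((k - 1) * dh + 1):(k * dh)
    Pk <- P[, cols, drop = FALSE]
    es <- as.numeric(Pk %*% aSrc[k, ])
    ed <- as.numeric(Pk %*% aDst[k, ])
    ePre <- es[src] + ed[dst]
    eNeg <- ePre < 0
    eAct <- ePre
    eAct[eNeg] <- slope * ePre[eNeg]
    ## softmax over each destination's neighborhood; global-max
    ## stabilization, per-group denominators via rowsum
    ex <- exp(eAct - max(eAct))
    dsum <- rowsum(ex, dst)
    denom <- numeric(M)
    denom[as.integer(rownames(dsum))] <- dsum
    alpha <- ex / denom[dst]
    agg <- rowsum(Pk[src, , drop = FALSE] * alpha, dst)
    out[as.integer(rownames(agg)), cols] <- agg
    hc[[k]] <- list(alpha = alpha, eNeg = eNeg, cols = cols)
  }
  list(out = out, P = P, H = H, W = W, aSrc = aSrc, aDst = aDst,
       edges = edges, heads = heads, dh = dh, slope = slope, hc = hc)
}

.nnGatBwd <- function(dOut, cache) {
  H <- cache$H; W <- cache$W; P <- cache$P
  src <- cache$edges[, 1]; dst <- cache$edges[, 2]
  heads <- cache$heads
  slope <- cache$slope
  dP <- matrix(0, nrow(P), ncol(P))
  daSrc <- matrix(0, heads, cache$dh)
  daDst <- matrix(0, heads, cache$dh)
  for (k in seq_len(heads)) {
    hcK <- cache$hc[[k]]
    cols <- hcK$cols
    alpha <- hcK$alpha
    Pk <- P[, cols, drop = FALSE]
    dOk <- dOut[, cols, drop = FALSE]
    ## value path: out[j] = sum_e alpha_e P[src_e]
    dAlpha <- rowSums(dOk[dst, , drop = FALSE] * Pk[src, , drop = FALSE])
    dPk <- rowsum(dOk[dst, , drop = FALSE] * alpha, src)
    dPval <- matrix(0, nrow(P), cache$dh)
    dPval[as.integer(rownames(dPk)), ] <- dPk
    ## per-destination softmax backward
    isum <- rowsum(alpha * dAlpha, dst)
    innerByNode <- numeric(nrow(P))
    innerByNode[as.integer(rownames(isum))] <- isum
    dEact <- alpha * (dAlpha - innerByNode[dst])
    dEpre <- dEact
    dEpre[hcK$eNeg] <- slope * dEact[hcK$eNeg]
    ## ePre = es[src] + ed[dst]; es = Pk aSrc ; ed = Pk aDst
    dEs <- rowsum(dEpre, src)
    dEd <- rowsum(dEpre, dst)
    dEsFull <- numeric(nrow(P)); dEsFull[as.integer(rownames(dEs))] <- dEs
    dEdFull <- numeric(nrow(P)); dEdFull[as.integer(rownames(dEd))] <- dEd
    daSrc[k, ] <- as.numeric(crossprod(Pk, dEsFull))
    daDst[k, ] <- as.numeric(crossprod(Pk, dEdFull))
    dPatt <- outer(dEsFull, cache$aSrc[k, ]) + outer(dEdFull, cache$aDst[k, ])
    dP[, cols] <- dPval + dPatt
  }
  list(dH = tcrossprod(dP, W), dW = crossprod(H, dP), daSrc = daSrc, daDst = daDst)
}

## ---------------------------------------------------------------------------
## Global multi-head self-attention over all nodes (the transformer layer).

.nnSelfAttnFwd <- function(X, Wq, Wk, Wv, heads, attnDropout, train) {
  M <- nrow(X)
  d <- ncol(Wq)
  dh <- d / heads
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  out <- matrix(0, M, d)
  hc <- vector("list", heads)
  for (k in seq_len(heads)) {
    cols <- ((k - 1) * dh + 1):(k * dh)
    Qk <- Q[, cols, drop = FALSE]; Kk <- K[, cols, drop = FALSE]
    Vk <- V[, cols, drop = FALSE]
    S <- tcrossprod(Qk, Kk) / sqrt(dh)
    A <- .rowSoftmax(S)
    dp <- .nnDropoutFwd(A, attnDropout, train)
    out[, cols] <- dp$out %*% Vk
    hc[[k]] <- list(A = A, mask = dp$mask, cols = cols)
  }
  list(out = out, X = X, Q = Q, K = K, V = V, Wq = Wq, Wk = Wk, Wv = Wv,
       heads = heads, dh = dh, hc = hc)
}

.nnSelfAttnBwd <- function(dOut, cache) {
  X <- cache$X
  dh <- cache$dh
  dQ <- matrix(0, nrow(X), ncol(cache$Q))
  dK <- dQ; dV <- dQ
  for (k in seq_len(cache$heads)) {
    hcK <- cache$hc[[k]]
    cols <- hcK$cols
    A <- hcK$A
    Qk <- cache$Q[, cols, drop = FALSE]
    Kk <- cache$K[, cols, drop = FALSE]
    Vk <- cache$V[, cols, drop = FALSE]
    dOk <- dOut[, cols, drop = FALSE]
    Adrop <- if (is.null(hcK$mask)) A else A * hcK$mask
    dV[, cols] <- crossprod(Adrop, dOk)
    dAdrop <- tcrossprod(dOk, Vk)
    dA <- if (is.null(hcK$mask)) dAdrop else dAdrop * hcK$mask
    dS <- A * (dA - .rowSums(dA * A, nrow(A), ncol(A)))
    dS <- dS / sqrt(dh)
    dQ[, cols] <- dS %*% Kk
    dK[, cols] <- crossprod(dS, Qk)
  }
  list(dX = tcrossprod(dQ, cache$Wq) + tcrossprod(dK, cache$Wk) +
         tcrossprod(dV, cache$Wv),
       dWq = crossprod(X, dQ), dWk = crossprod(X, dK), dWv = crossprod(X, dV))
}

## ---------------------------------------------------------------------------
## Dual cross-attention between one drug vector and one gene vector per
## pair. Each embedding is viewed as `heads` tokens of width dk (the head
## dimension), so the attention map per direction is heads x heads with
## rows that are probability distributions; scale is 1/sqrt(dk).

## Head-token attention between two batched vector sets, vectorized over
## the batch. Q, K, V are B x d with d = heads * dh; token i of a row is
## its i-th head block. Returns the attended output (B x d), the
## attention tensors (B x heads x heads) and the dropout mask.
.headTokenAttn <- function(Q, K, V, heads, dh, attnDropout, train) {
  B <- nrow(Q)
  colsOf <- function(i) ((i - 1) * dh + 1):(i * dh)
  ## block aggregation matrix: column k of head i sums into slot i
  Agg <- kronecker(diag(heads), matrix(1, dh, 1))
  ## S[b, i, j] = <Q_head_i(b), K_head_j(b)> / sqrt(dh)
  S <- array(0, c(B, heads, heads))
  for (j in seq_len(heads)) {
    Ktile <- K[, rep(colsOf(j), heads), drop = FALSE]
    S[, , j] <- ((Q * Ktile) %*% Agg) / sqrt(dh)
  }
  ## row softmax over j for every (b, i)
  Sm <- matrix(S, B * heads, heads)
  Am <- .rowSoftmax(Sm)
  dp <- .nnDropoutFwd(Am, attnDropout, train)
  Adrop <- array(dp$out, c(B, heads, heads))
  O <- matrix(0, B, heads * dh)
  for (i in seq_len(heads)) {
    acc <- matrix(0, B, dh)
    for (j in seq_len(heads))
      acc <- acc + Adrop[, i, j] * V[, colsOf(j), drop = FALSE]
    O[, colsOf(i)] <- acc
  }
  list(O = O, A = array(Am, c(B, heads, heads)), Am = Am, mask = dp$mask,
       Adrop = Adrop)
}

.headTokenAttnBwd <- function(dO, att, Q, K, V, heads, dh) {
  B <- nrow(dO)
  colsOf <- function(i) ((i - 1) * dh + 1):(i * dh)
  Agg <- kronecker(diag(heads), matrix(1, dh, 1))
  dAdrop <- array(0, c(B, heads, heads))
  dV <- matrix(0, B, heads * dh)
  for (j in seq_len(heads)) {
    Vtile <- V[, rep(colsOf(j), heads), drop = FALSE]
    dAdrop[, , j] <- (dO * Vtile) %*% Agg
    accV <- matrix(0, B, dh)
    for (i in seq_len(heads))
      accV <- accV + att$Adrop[, i, j] * dO[, colsOf(i), drop = FALSE]
    dV[, colsOf(j)] <- accV
  }
  dAm <- matrix(dAdrop, B * heads, heads)
  if (!is.null(att$mask)) dAm <- dAm * att$mask
  A <- att$Am
  dSm <- A * (dAm - .rowSums(dAm * A, nrow(A), ncol(A))) / sqrt(dh)
  dS <- array(dSm, c(B, heads, heads))
  dQ <- matrix(0, B, heads * dh)
  dK <- matrix(0, B, heads * dh)
  for (i in seq_len(heads)) {
    accQ <- matrix(0, B, dh)
    for (j in seq_len(heads))
      accQ <- accQ + dS[, i, j] * K[, colsOf(j), drop = FALSE]
    dQ[, colsOf(i)] <- accQ
  }
  for (j in seq_len(heads)) {
    accK <- matrix(0, B, dh)
    for (i in seq_len(heads))
      accK <- accK + dS[, i, j] * Q[, colsOf(i), drop = FALSE]
    dK[, colsOf(j)] <- accK
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

.nnCrossAttnFwd <- function(Hm, Z, prm, heads, attnDropout, train) {
  d <- ncol(Hm)
  dh <- d / heads
  Qd <- Hm %*% prm$dWq; Kg <- Z %*% prm$gWk; Vg <- Z %*% prm$gWv
  Qg <- Z %*% prm$gWq; Kd <- Hm %*% prm$dWk; Vd <- Hm %*% prm$dWv
  a1 <- .headTokenAttn(Qd, Kg, Vg, heads, dh, attnDropout, train)
  a2 <- .headTokenAttn(Qg, Kd, Vd, heads, dh, attnDropout, train)
  B <- nrow(Hm)
  list(fused = cbind(a1$O, a2$O),
       attnDG = lapply(seq_len(B), function(b) a1$A[b, , ]),
       attnGD = lapply(seq_len(B), function(b) a2$A[b, , ]),
       Hm = Hm, Z = Z, prm = prm, heads = heads, dh = dh,
       Qd = Qd, Kg = Kg, Vg = Vg, Qg = Qg, Kd = Kd, Vd = Vd,
       a1 = a1, a2 = a2)
}

.nnCrossAttnBwd <- function(dFused, cache) {
  d <- ncol(dFused) / 2
  heads <- cache$heads
  dh <- cache$dh
  g1 <- .headTokenAttnBwd(dFused[, 1:d, drop = FALSE], cache$a1,
                          cache$Qd, cache$Kg, cache$Vg, heads, dh)
  g2 <- .headTokenAttnBwd(dFused[, (d + 1):(2 * d), drop = FALSE], cache$a2,
                          cache$Qg, cache$Kd, cache$Vd, heads, dh)
  prm <- cache$prm
  Hm <- cache$Hm; Z <- cache$Z
  list(
    dHm = tcrossprod(g1$dQ, prm$dWq) + tcrossprod(g2$dK, prm$dWk) +
      tcrossprod(g2$dV, prm$dWv),
    dZ = tcrossprod(g1$dK, prm$gWk) + tcrossprod(g1$dV, prm$gWv) +
      tcrossprod(g2$dQ, prm$gWq),
    grads = list(
      dWq = crossprod(Hm, g1$dQ), dWk = crossprod(Hm, g2$dK),
      dWv = crossprod(Hm, g2$dV), gWq = crossprod(Z, g2$dQ),
      gWk = crossprod(Z, g1$dK), gWv = crossprod(Z, g1$dV)
    )
  )
}

## ---------------------------------------------------------------------------
## Xavier-uniform initializer.
.xavier <- function(fanIn, fanOut, nrow = fanIn, ncol = fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}
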