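test_that("encoder outputs have the contracted shapes and eval mode is deterministic", {
  tm <- tinyModel()
  b <- tinyBatch()
  enc1 <- encodeMolecules(tm$model, b$fp, b$de)
  enc2 <- encodeMolecules(tm$model, b$fp, b$de)
  expect_equal(dim(enc1$hmol), c(5, 8))
  expect_equal(enc1$hmol, enc2$hmol, tolerance = 1e-12)
  ## identical input rows give identical embeddings
  fpDup <- b$fp[c(1, 1, 2), ]
  deDup <- b$de[c(1, 1, 2), ]
  e <- encodeMolecules(tm$model, fpDup, deDup)
  expect_equal(e$hmol[1, ], e$hmol[2, ], tolerance = 1e-12)
  ## degenerate input stays finite
  e0 <- encodeMolecules(tm$model, matrix(0, 1, 6), matrix(0, 1, 3))
  expect_true(all(is.finite(e0$hmol)))
  expect_error(encodeMolecules(tm$model, b$fp[, 1:3], b$de), "widths")

  gen <- encodeGenes(tm$model)
  expect_equal(dim(gen$z), c(8, 8))
  expect_equal(rownames(gen$z), tm$model@genes)
})

test_that("graph-attention weights are probability distributions over neighborhoods", {
  tm <- tinyModel()
  gen <- encodeGenes(tm$model)
  g1 <- gen$cache$g1
  dst <- tm$model@edges[, 2]
  for (k in seq_along(g1$hc)) {
    sums <- tapply(g1$hc[[k]]$alpha, dst, sum)
    expect_equal(unname(as.numeric(sums)), rep(1, length(sums)),
                 tolerance = 1e-6)
  }
})

test_that("gene encoding is permutation-equivariant in evaluation mode", {
  tm <- tinyModel()
  z1 <- encodeGenes(tm$model)$z
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  m2 <- tm$model
  m2@genes <- tm$model@genes[perm]
  inv <- order(perm)
  m2@edges <- matrix(inv[tm$model@edges], ncol = 2)
  m2@clusterOneHot <- tm$model@clusterOneHot[perm, , drop = FALSE]
  m2@params$E <- tm$model@params$E[perm, , drop = FALSE]
  z2 <- encodeGenes(m2)$z
  expect_equal(z2[tm$model@genes, ], z1[tm$model@genes, ], tolerance = 1e-9)
})

test_that("cross-attention maps are row-stochastic and the fused width doubles dModel", {
  tm <- tinyModel()
  b <- tinyBatch()
  enc <- encodeMolecules(tm$model, b$fp, b$de)
  z <- encodeGenes(tm$model)$z[b$geneIdx, , drop = FALSE]
  ca <- crossAttend(tm$model, enc$hmol, z)
  expect_equal(ncol(ca$fused), 16)
  for (A in c(ca$attnDG, ca$attnGD))
    expect_equal(unname(rowSums(A)), rep(1, nrow(A)), tolerance = 1e-6)
  ## attention scale is 1/sqrt(dk); dk = 64 gives the documented 1/8
  cfg512 <- dtiModelConfig(dModel = 512, heads = 8)
  expect_equal(cfg512$dk, 64)
  expect_equal(cfg512$attnScale, 1 / 8)
})

test_that("score and uncertainty respect their ranges and determinism", {
  tm <- tinyModel()
  b <- tinyBatch(B = 40)
  enc <- encodeMolecules(tm$model, b$fp, b$de)
  z <- encodeGenes(tm$model)$z[b$geneIdx, , drop = FALSE]
  ca <- crossAttend(tm$model, enc$hmol, z)
  so <- scoreInteraction(tm$model, ca$fused)
  expect_true(all(so$s >= 0 & so$s <= 1))
  expect_true(all(so$u >= 0 & so$u < 0.5))
  so2 <- scoreInteraction(tm$model, ca$fused)
  expect_equal(so$s, so2$s, tolerance = 1e-12)
  expect_equal(so$u, so2$u, tolerance = 1e-12)
  expect_error(scoreInteraction(tm$model, ca$fused[, 1:10]), "2 \\* dModel")
})

test_that("MC dropout: zero variance without dropout, positive with, reproducible via seed", {
  tmDet <- tinyModel(dropout = 0, attnDropout = 0)
  b <- tinyBatch()
  genes <- tmDet$model@genes[b$geneIdx]
  p0 <- predictMC(tmDet$model, b$fp, b$de, genes, T = 6, seed = 2)
  expect_equal(p0$sigma2, rep(0, 5), tolerance = 1e-15)

  tmSto <- tinyModel(dropout = 0.2, attnDropout = 0.1)
  p1 <- predictMC(tmSto$model, b$fp, b$de, genes, T = 6, seed = 2)
  p2 <- predictMC(tmSto$model, b$fp, b$de, genes, T = 6, seed = 2)
  expect_gt(max(p1$sigma2), 0)
  expect_equal(p1$sbar, p2$sbar, tolerance = 1e-12)
  expect_equal(p1$sigma2, p2$sigma2, tolerance = 1e-12)
  expect_error(predictMC(tmSto$model, b$fp, b$de, genes, T = 0), "T must")
})

test_that("every parameter receives a nonzero gradient on a random batch", {
  tm <- tinyModel(dropout = 0.1, attnDropout = 0.05, seed = 19)
  b <- tinyBatch(B = 12)
  gl <- as.numeric(tm$model@clusterOneHot[, 1])
  set.seed(33)
  bg <- GraphDTI:::.batchGrads(tm$model, b$fp, b$de, b$geneIdx,
                               rbinom(12, 1, 0.5), gl,
                               dtiTrainConfig(lambdaU = 0.1, lambdaG = 0.5,
                                              lambdaR = 0.5))
  for (nm in names(bg$grads))
    expect_gt(max(abs(bg$grads[[nm]])), 0, label = paste("grad", nm))
})

test_that("analytic gradients agree with central finite differences", {
  tm <- tinyModel(dropout = 0, attnDropout = 0)
  b <- tinyBatch(B = 4)
  gl <- as.numeric(tm$model@clusterOneHot[, 1])
  y <- c(1, 0, 1, 0)
  tcfg <- dtiTrainConfig(lambdaU = 0.1, lambdaG = 0.7, lambdaR = 0.5)
  lossAt <- function(params) {
    m <- tm$model
    m@params <- params
    GraphDTI:::.batchGrads(m, b$fp, b$de, b$geneIdx, y, gl, tcfg)$loss
  }
  bg <- GraphDTI:::.batchGrads(tm$model, b$fp, b$de, b$geneIdx, y, gl, tcfg)
  eps <- 1e-6
  set.seed(55)
  for (nm in sample(names(tm$model@params))) {
    p <- tm$model@params
    i <- sample(length(p[[nm]]), 1)
    x0 <- p[[nm]][i]
    p[[nm]][i] <- x0 + eps; lp <- lossAt(p)
    p[[nm]][i] <- x0 - eps; lm <- lossAt(p)
    num <- (lp - lm) / (2 * eps)
    ana <- bg$grads[[nm]][i]
    expect_lt(abs(num - ana), 1e-6 + 1e-3 * (abs(num) + abs(ana)),
              label = paste("fd grad", nm))
  }
})

test_that("model checkpoints round-trip through the JSON serialization", {
  tm <- tinyModel()
  b <- tinyBatch()
  path <- tempfile(fileext = ".json")
  saveDTIModel(tm$model, path)
  m2 <- loadDTIModel(path)
  genes <- tm$model@genes[b$geneIdx]
  expect_equal(predictPairs(tm$model, b$fp, b$de, genes)$s,
               predictPairs(m2, b$fp, b$de, genes)$s, tolerance = 1e-12)
})
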