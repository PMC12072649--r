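makeInteractions <- function(n = 1000, posRate = 0.1, seed = 31) {
  set.seed(seed)
  data.frame(drug_id = sprintf("d%04d", seq_len(n)),
             gene_id = sprintf("g%03d", sample(50, n, replace = TRUE)),
             label = rbinom(n, 1, posRate), stringsAsFactors = FALSE)
}

test_that("the 70/10/20 split is exact, stratified and reproducible", {
  df <- makeInteractions(1000)
  df$label <- rep(c(1, 0), c(100, 900))   # exactly 10% positives
  sp <- splitDataset(df, seed = 4)
  expect_equal(unname(table(sp$split)[c("train", "val", "test")]),
               c(700, 100, 200), ignore_attr = TRUE)
  glob <- mean(sp$label)
  for (tag in c("train", "val", "test"))
    expect_lt(abs(mean(sp$label[sp$split == tag]) - glob), 0.02)
  sp2 <- splitDataset(df, seed = 4)
  expect_identical(sp$split, sp2$split)
  expect_error(splitDataset(df[1:3, ], fractions = c(0.7, 0.1, 0.2)), "empty")
})

test_that("interaction loss reproduces its arithmetic and degenerate identities", {
  s <- c(0.9, 0.2); y <- c(1, 0); u <- c(0.5, 1.0)
  ## frozen by-hand evaluation: BCE terms -log(0.9), -log(0.8);
  ## sum(BCE/u) + 0.1 * sum(log u)
  byHand <- (-log(0.9) / 0.5) + (-log(0.8) / 1.0) + 0.1 * (log(0.5) + log(1))
  expect_equal(lossDti(s, y, u, lambdaU = 0.1), byHand, tolerance = 1e-12)
  ## u = 1 collapses to plain summed BCE
  expect_equal(lossDti(s, y, c(1, 1), lambdaU = 0.1),
               -log(0.9) - log(0.8), tolerance = 1e-12)
  ## near-perfect predictions, unit u -> near-zero loss
  expect_lt(lossDti(c(1 - 1e-9, 1e-9), y, c(1, 1), 0.1), 1e-6)
  expect_error(lossDti(c(NA, 0.5), y, u), "NaN/NA")
})

test_that("gene and reconstruction losses match scalar oracles", {
  p <- c(0.8, 0.3, 0.6); y <- c(1, 0, 1)
  byHand <- -(log(0.8) + log(0.7) + log(0.6))
  expect_equal(lossGene(p, y, lambdaG = 1), byHand, tolerance = 1e-12)
  expect_equal(lossGene(p, y, lambdaG = 0), 0)
  expect_lt(lossGene(c(1 - 1e-9, 1e-9, 1 - 1e-9), y, 1), 1e-6)

  f <- c(1, 0, 0, 1); fpHat <- c(0.9, 0.1, 0.2, 0.8)
  d <- c(0.5, -1); dHat <- c(0.4, -0.8)
  bce <- mean(-(f * log(fpHat) + (1 - f) * log(1 - fpHat)))
  mse <- mean((dHat - d)^2)
  expect_equal(lossRecon(fpHat, f, dHat, d, lambdaR = 2, "bce_mse"),
               2 * (bce + mse), tolerance = 1e-12)
  expect_equal(lossRecon(fpHat, f, dHat, d, lambdaR = 2, "eq_l1_l2"),
               2 * (sum(abs(fpHat - f)) + sum((dHat - d)^2)), tolerance = 1e-12)
  ## perfect reconstruction is exactly zero under the norm variant
  expect_equal(lossRecon(f, f, d, d, lambdaR = 1, "eq_l1_l2"), 0)
  expect_equal(lossRecon(fpHat, f, dHat, d, lambdaR = 0), 0)
  expect_error(lossRecon(fpHat, f, dHat, d[1]), "widths")
})

test_that("evaluation metrics: rank AUROC, F1 identity, null behavior", {
  ## perfect separation
  ev <- evaluateScores(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(ev$auroc, 1)
  expect_equal(ev$f1, 1)
  ## cross-check against an independent AUROC implementation
  set.seed(41)
  sc <- runif(300); lb <- rbinom(300, 1, 0.4)
  ours <- evaluateScores(sc, lb)$auroc
  ref <- as.numeric(suppressMessages(pROC::auc(lb, sc, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
  ## F1 is always the harmonic mean of precision and recall
  for (rep in 1:5) {
    sc <- runif(200); lb <- rbinom(200, 1, 0.3)
    ev <- evaluateScores(sc, lb)
    if (ev$precision + ev$recall > 0)
      expect_equal(ev$f1, 2 * ev$precision * ev$recall /
                     (ev$precision + ev$recall), tolerance = 1e-12)
  }
  ## random scores on balanced labels concentrate at AUROC 0.5
  set.seed(42)
  ev <- evaluateScores(runif(10000), rbinom(10000, 1, 0.5))
  expect_lt(abs(ev$auroc - 0.5), 0.02)
  ## single-class split
  expect_true(is.na(evaluateScores(runif(5), rep(1, 5))$auroc))
})

test_that("a few epochs on a tiny separable task reduce the loss and stopping honors patience", {
  set.seed(51)
  cfg <- syntheticConfig(nGenes = 30, K = 3, nDrugs = 40, pIn = 0.4,
                         pOut = 0.03, nBits = 32, nDesc = 8,
                         pairsPerDrug = 10)
  bench <- generateBenchmark(cfg, seed = 5)
  inter <- splitDataset(bench$interactions, seed = 5)
  model <- initDTIModel(bench$graph, bench$truePartition, cfg$nBits,
                        cfg$nDesc, dtiModelConfig(dModel = 16, heads = 4),
                        seed = 5)
  tcfg <- dtiTrainConfig(maxEpochs = 6, patience = 3, seed = 5)
  fit <- trainDTIModel(model, bench$lib, inter, bench$geneLabels, tcfg)
  h <- fit@meta$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_lte(nrow(h) - fit@meta$bestEpoch, tcfg$patience)
  ## same seed, same history
  fit2 <- trainDTIModel(model, bench$lib, inter, bench$geneLabels, tcfg)
  expect_equal(fit@meta$history$loss, fit2@meta$history$loss, tolerance = 1e-10)
  ## no positives in train -> error
  bad <- inter
  bad$label[bad$split == "train"] <- 0
  expect_error(trainDTIModel(model, bench$lib, bad, bench$geneLabels, tcfg),
               "no positive labels")
})
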