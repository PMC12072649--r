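## records fixture with fully controlled values
makeRecords <- function(drugs, genes, sbar, sigma2 = 0, u = 0,
                        cluster = NULL) {
  df <- expand.grid(gene_id = genes, drug_id = drugs,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("drug_id", "gene_id")]
  df$cluster <- if (is.null(cluster)) "0" else cluster[df$gene_id]
  df$sbar <- sbar
  df$sigma2 <- sigma2
  df$u <- u
  df$probability_pct <- 100 * df$sbar
  df
}

test_that("screening yields one MC record per (drug, target) with bounded uncertainty", {
  tm <- tinyModel(dropout = 0.2, attnDropout = 0.1)
  set.seed(61)
  lib <- drugLibrary(sprintf("d%02d", 1:10),
                     matrix(rbinom(10 * 6, 1, 0.4), 10, 6),
                     matrix(rnorm(10 * 3), 10, 3))
  targets <- list("0" = tm$model@genes[1:3], "1" = tm$model@genes[5:6])
  rec <- screenLibrary(tm$model, lib, targets, batch = 4, T = 4, seed = 9)
  expect_equal(nrow(rec), 10 * 5)
  expect_setequal(unique(rec$cluster), c("0", "1"))
  expect_true(all(rec$u <= 0.5))
  expect_true(all(rec$sbar >= 0 & rec$sbar <= 1))
  expect_error(screenLibrary(tm$model, lib, character(0)), "empty target")
})

test_that("evaluation-mode predictions are independent of batch composition", {
  tm <- tinyModel(dropout = 0, attnDropout = 0)
  set.seed(62)
  lib <- drugLibrary(sprintf("d%02d", 1:9),
                     matrix(rbinom(9 * 6, 1, 0.4), 9, 6),
                     matrix(rnorm(9 * 3), 9, 3))
  targets <- tm$model@genes[1:2]
  r1 <- screenLibrary(tm$model, lib, targets, batch = 3, T = 1, seed = 1)
  r2 <- screenLibrary(tm$model, lib, targets, batch = 9, T = 1, seed = 1)
  key <- paste(r1$drug_id, r1$gene_id)
  expect_equal(r1$sbar, r2$sbar[match(key, paste(r2$drug_id, r2$gene_id))],
               tolerance = 1e-6)
})

test_that("z-scores use the population deviation per gene and percentiles follow rank", {
  rec <- makeRecords(sprintf("d%d", 1:4), "gA", sbar = c(1, 2, 3, 4) / 10)
  out <- normalizeScores(rec)
  expect_equal(sort(out$z), c(-1.3416408, -0.4472136, 0.4472136, 1.3416408),
               tolerance = 1e-6)
  expect_equal(out$percentile[which.max(out$sbar)], 100)
  expect_equal(out$percentile[which.min(out$sbar)], 25)
  ## centering: a record at the gene mean has z = 0
  rec2 <- makeRecords(sprintf("d%d", 1:3), "gA", sbar = c(0.1, 0.2, 0.3))
  expect_equal(normalizeScores(rec2)$z[2], 0, tolerance = 1e-12)
  ## affine invariance of z
  recA <- makeRecords(sprintf("d%d", 1:5), "gA", sbar = c(5, 1, 3, 2, 4))
  recB <- recA; recB$sbar <- 10 * recB$sbar + 2
  expect_equal(normalizeScores(recA)$z, normalizeScores(recB)$z,
               tolerance = 1e-9)
  ## zero variance -> z = 0 with warning
  recC <- makeRecords(sprintf("d%d", 1:3), "gA", sbar = 0.5)
  expect_warning(outC <- normalizeScores(recC), "zero score variance")
  expect_equal(outC$z, rep(0, 3))
})

test_that("uncertainty filter keeps confident records and relaxes only when too few drugs pass", {
  rec <- makeRecords(sprintf("d%02d", 1:12), "gA", sbar = 0.5, u = 0.3)
  f <- filterByUncertainty(rec)
  expect_equal(nrow(f$records), 12)
  expect_false(f$relaxed)
  expect_equal(f$tau, 0.5)
  ## 5 drugs below 0.5 and 20 in (0.5, 0.7): relaxation admits all 25
  rec2 <- makeRecords(sprintf("d%02d", 1:25), "gA", sbar = 0.5,
                      u = c(rep(0.3, 5), rep(0.6, 20)))
  f2 <- filterByUncertainty(rec2)
  expect_true(f2$relaxed)
  expect_equal(f2$tau, 0.7)
  expect_equal(nrow(f2$records), 25)
  ## idempotence of the filter on its own output
  f3 <- filterByUncertainty(f2$records)
  expect_equal(nrow(f3$records), nrow(f2$records))
  ## empty input passes through
  expect_equal(nrow(filterByUncertainty(rec[0, ])$records), 0)
})

test_that("ranking follows the penalized-affinity formula with deterministic ties", {
  drugs <- c("dA", "dB", "dC")
  rec <- makeRecords(drugs, c("g1", "g2"),
                     sbar = c(0.9, 0.7, 0.6, 0.8, 0.5, 0.6),
                     sigma2 = c(0.04, 0.04, 0, 0.01, 0.01, 0.09),
                     u = c(0.3, 0.1, 0.2, 0.2, 0.1, 0.4))
  rk <- rankDrugs(rec, c("g1", "g2"), lambdaPenalty = 1)
  ## frozen by-hand evaluation of the formula per drug
  byHand <- sapply(drugs, function(d) {
    r <- rec[rec$drug_id == d, ]
    mean(r$sbar) - mean(sqrt(r$u^2 + r$sigma2))
  })
  expect_equal(rk$rankScore, unname(sort(byHand, decreasing = TRUE)),
               tolerance = 1e-12)
  ## lambda = 0 reduces to mean-score ordering
  rk0 <- rankDrugs(rec, c("g1", "g2"), lambdaPenalty = 0)
  aff <- sapply(drugs, function(d) mean(rec$sbar[rec$drug_id == d]))
  expect_equal(rk0$drug_id, names(sort(aff, decreasing = TRUE)))
  ## zero uncertainty: rank score equals the mean score exactly
  recZ <- makeRecords(drugs, c("g1", "g2"), sbar = runif(6))
  rkZ <- rankDrugs(recZ, c("g1", "g2"), lambdaPenalty = 1)
  expect_equal(rkZ$rankScore, rkZ$affinity, tolerance = 1e-12)
  expect_error(rankDrugs(rec[-1, ], c("g1", "g2")), "missing \\(drug, target\\)")
})

test_that("a larger penalty never improves the most-uncertain drug's rank", {
  set.seed(63)
  rec <- makeRecords(sprintf("d%02d", 1:8), c("g1", "g2"),
                     sbar = runif(16), sigma2 = runif(16, 0, 0.05),
                     u = runif(16, 0, 0.4))
  totals <- tapply(sqrt(rec$u^2 + rec$sigma2), rec$drug_id, mean)
  worst <- names(which.max(totals))
  lams <- c(0, 0.5, 1, 2, 5)
  pos <- sapply(lams, function(l)
    which(rankDrugs(rec, c("g1", "g2"), l)$drug_id == worst))
  expect_true(all(diff(pos) >= 0))
})

test_that("multi-target extraction requires two genes in two distinct clusters", {
  cl <- c(gA = "0", gB = "1", gC = "1")
  rec <- makeRecords(sprintf("d%02d", 1:20), c("gA", "gB", "gC"),
                     sbar = runif(60, 0.1, 0.3), cluster = cl)
  ## dX: high on two clusters; dY: high twice within one cluster
  rec$sbar[rec$drug_id == "d01" & rec$gene_id %in% c("gA", "gB")] <- 0.95
  rec$sbar[rec$drug_id == "d02" & rec$gene_id %in% c("gB", "gC")] <- 0.95
  out <- findMultitarget(normalizeScores(rec), zThreshold = 2.8)
  expect_equal(out$drug_id, "d01")
  expect_setequal(strsplit(out$targets, ";")[[1]], c("gA", "gB"))
  expect_error(findMultitarget(rec), "normalized")
})
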