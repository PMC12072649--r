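test_that("z-scores have mean 0 / variance 1 and the inverted set flips sign", {
  set.seed(5)
  g <- randomConnectedGraph(20, 0.2)
  ct <- computeCentralities(g)
  fr <- standardizeMetrics(ct)
  z <- fciZscores(fr)
  raw <- as.matrix(centralityMetrics(ct))
  for (m in colnames(z)) {
    if (sd(raw[, m]) < 1e-12) next
    expect_equal(mean(z[, m]), 0, tolerance = 1e-9)
    expect_equal(var(z[, m]), 1, tolerance = 1e-9)
  }
  ## path center has the smallest mean path length -> positive z after
  ## inversion
  frPath <- suppressWarnings(standardizeMetrics(computeCentralities(pathGraph3())))
  expect_gt(fciZscores(frPath)["b", "avg_shortest_path"], 0)
  ## non-inverted metric keeps its orientation
  expect_gt(fciZscores(frPath)["b", "degree"], 0)
})

test_that("constant metric columns standardize to zero with a warning", {
  ct <- computeCentralities(triangleGraph())
  expect_warning(fr <- standardizeMetrics(ct), "zero-variance")
  expect_true(all(fciZscores(fr)[, "degree"] == 0))
})

test_that("FCI is a weight-normalized fusion: rescaling invariance and single-metric identity", {
  set.seed(6)
  g <- randomConnectedGraph(15, 0.25)
  ct <- computeCentralities(g)
  w1 <- fciWeights()
  w2 <- fciWeights(setNames(3 * w1@weights, names(w1@weights)))
  expect_equal(fciScores(computeFCI(ct, w1)), fciScores(computeFCI(ct, w2)),
               tolerance = 1e-12)
  ## all weight on closeness -> FCI equals the closeness z-score
  wSolo <- fciWeights(setNames(c(1, rep(0, 9)),
                               c("closeness", setdiff(names(w1@weights), "closeness"))))
  frSolo <- computeFCI(ct, wSolo)
  expect_equal(unname(fciScores(frSolo)),
               unname(fciZscores(frSolo)[, "closeness"]), tolerance = 1e-12)
  ## zero total weight rejected at construction
  expect_error(fciWeights(setNames(rep(0, 10), names(w1@weights))))
})

test_that("the star-graph hub attains the maximal FCI", {
  fr <- suppressWarnings(computeFCI(computeCentralities(starGraph(8))))
  expect_equal(names(which.max(fciScores(fr))), "hub")
})

test_that("FCI-metric correlations match a textbook Pearson implementation", {
  set.seed(8)
  for (rep in 1:5) {
    g <- randomConnectedGraph(18, 0.2)
    ct <- computeCentralities(g)
    fr <- suppressWarnings(computeFCI(ct))
    rep_ <- correlateFCI(fr, ct)
    raw <- centralityMetrics(ct)
    for (i in seq_len(nrow(rep_))) {
      m <- rep_$metric[i]
      if (sd(raw[[m]]) < 1e-12) {
        expect_true(is.na(rep_$r[i]))
      } else {
        expect_equal(rep_$r[i], oraclePearson(fciScores(fr), raw[[m]]),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("FCI correlates r = 1 with itself and with its single source metric", {
  set.seed(9)
  g <- randomConnectedGraph(15, 0.25)
  ct <- computeCentralities(g)
  wSolo <- fciWeights(setNames(c(1, rep(0, 9)),
                               c("closeness",
                                 setdiff(colnames(ct@metrics), "closeness"))))
  fr <- computeFCI(ct, wSolo)
  expect_equal(oraclePearson(fciScores(fr), fciScores(fr)), 1, tolerance = 1e-12)
  rep_ <- correlateFCI(fr, ct)
  expect_equal(rep_$r[rep_$metric == "closeness"], 1, tolerance = 1e-9)
})
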