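test_that("the degenerate block model gives two cliques and sampling is reproducible", {
  cfg <- syntheticConfig(nGenes = 12, K = 2, pIn = 1, pOut = 0.3,
                         nDrugs = 10)
  net <- generateNetwork(cfg, seed = 2)
  mem <- communityMembership(net$truePartition)
  A <- adjacencyMatrix(net$graph)
  for (lab in unique(mem)) {
    idx <- names(mem)[mem == lab]
    sub <- A[idx, idx]
    expect_true(all(sub[upper.tri(sub)] == 1))   # within-block: clique
  }
  net2 <- generateNetwork(cfg, seed = 2)
  expect_identical(adjacencyMatrix(net2$graph), A)
})

test_that("realized within-cluster edge density approaches pIn", {
  cfg <- syntheticConfig(nGenes = 200, K = 5, pIn = 0.3, pOut = 0.02)
  net <- generateNetwork(cfg, seed = 6)
  mem <- communityMembership(net$truePartition)
  A <- adjacencyMatrix(net$graph)
  dens <- sapply(unique(mem), function(lab) {
    idx <- names(mem)[mem == lab]
    sub <- A[idx, idx]
    mean(sub[upper.tri(sub)])
  })
  expect_true(all(abs(dens - cfg$pIn) < 0.05))
})

test_that("drug features are binary/reproducible and descriptors are low-rank plus noise", {
  cfg <- syntheticConfig(nDrugs = 150, latentDim = 8, nDesc = 16,
                         noiseSd = 0.05)
  net <- generateNetwork(cfg, seed = 3)
  d1 <- generateDrugs(cfg, net$centroids, seed = 3)
  d2 <- generateDrugs(cfg, net$centroids, seed = 3)
  expect_identical(drugFingerprints(d1$lib), drugFingerprints(d2$lib))
  expect_true(all(drugFingerprints(d1$lib) %in% c(0, 1)))
  expect_true(d1$multiTargetDrug %in% drugIds(d1$lib))
  ## descriptor spectrum: energy beyond latentDim is only the noise floor
  sv <- svd(scale(d1$lib@descriptors, scale = FALSE))$d
  tailEnergy <- sum(sv[(cfg$latentDim + 1):length(sv)]^2) / sum(sv^2)
  expect_lt(tailEnergy, 0.05)
})

test_that("interaction labels hit the calibrated positive rate and are seed-stable", {
  cfg <- syntheticConfig(nDrugs = 400, pairsPerDrug = 25)
  bench <- generateBenchmark(cfg, seed = 8)
  expect_gt(nrow(bench$interactions), 9000)
  expect_lt(abs(mean(bench$interactions$label) - 0.10), 0.02)
  bench2 <- generateBenchmark(cfg, seed = 8)
  expect_identical(bench$interactions$label, bench2$interactions$label)
  ## gene disease labels mark the designated cluster
  mem <- communityMembership(bench$truePartition)
  expect_equal(unname(bench$geneLabels[names(mem)]),
               unname(as.integer(mem == 0)))
})

test_that("the planted drug has above-median true affinity for targets in two clusters", {
  cfg <- syntheticConfig()
  bench <- generateBenchmark(cfg, seed = 4)
  mem <- communityMembership(bench$truePartition)
  dots <- bench$geneLatents %*% bench$drugLatents[bench$multiTargetDrug, ]
  for (cl in bench$multiTargetClusters) {
    genes <- names(mem)[mem == cl]
    ## affinity of the planted drug within the cluster clearly exceeds
    ## the library median affinity for those genes
    others <- bench$geneLatents[genes, , drop = FALSE] %*% t(bench$drugLatents)
    expect_gt(mean(dots[genes, ]), median(others))
  }
})
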