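test_that("modularity matrix matches the closed form on K3 and sums to zero", {
  B <- modularityMatrix(triangleGraph())
  expect_equal(unname(B[1, 2]), 1 - 4 / 6, tolerance = 1e-12)
  expect_equal(unname(diag(B)), rep(-4 / 6, 3), tolerance = 1e-12)
  expect_equal(sum(B), 0, tolerance = 1e-12)
  set.seed(12)
  for (rep in 1:5) {
    g <- randomConnectedGraph(sample(5:12, 1), 0.35)
    A <- adjacencyMatrix(g)
    k <- rowSums(A)
    m <- sum(k) / 2
    expect_equal(modularityMatrix(g), A - outer(k, k) / (2 * m),
                 tolerance = 1e-12)
    expect_equal(max(abs(rowSums(modularityMatrix(g)))), 0, tolerance = 1e-9)
  }
})

test_that("Q of the one-community partition is zero and Q(s) = s'Bs/4m for all sign vectors", {
  set.seed(13)
  g <- randomConnectedGraph(9, 0.3)
  nm <- nodeNames(g)
  expect_equal(modularityQ(g, setNames(rep(0L, 9), nm)), 0, tolerance = 1e-12)
  B <- modularityMatrix(g)
  m <- numEdges(g)
  for (mask in 0:(2^9 - 1)) {
    s <- ifelse(bitwAnd(mask, 2^(0:8)) > 0, 1, -1)
    mem <- setNames(as.integer(s > 0), nm)
    expect_equal(modularityQ(g, mem),
                 as.numeric(t(s) %*% B %*% s) / (4 * m), tolerance = 1e-12)
  }
})

test_that("missing labels are an error", {
  g <- triangleGraph()
  expect_error(modularityQ(g, c(a = 0L, b = 1L)), "missing a community label.*c")
})

test_that("leading-eigenvector bisection separates bridged cliques at the enumeration optimum", {
  g <- bridgedCliques()
  sp <- leadingEigenBisect(g)
  expect_true(sp$divisible)
  expect_equal(length(unique(sp$s[letters[1:4]])), 1)
  expect_equal(length(unique(sp$s[letters[5:8]])), 1)
  expect_true(sp$s["a"] != sp$s["e"])
  best <- enumerateBestBisection(g)
  expect_equal(sp$dQ, best$Q, tolerance = 1e-9)
})

test_that("complete graphs are indivisible; P4's split matches the enumeration optimum", {
  ig <- igraph::make_full_graph(5)
  igraph::V(ig)$name <- letters[1:5]
  sp <- leadingEigenBisect(GeneGraph(ig))
  expect_false(sp$divisible)

  p4 <- GeneGraph(cbind(c("a", "b", "c"), c("b", "c", "d")))
  sp4 <- leadingEigenBisect(p4)
  best <- enumerateBestBisection(p4)
  if (best$Q > 1e-12) {
    expect_true(sp4$divisible)
    expect_equal(sp4$dQ, best$Q, tolerance = 1e-9)
  } else expect_false(sp4$divisible)
})

test_that("bisection gain never exceeds the exhaustive two-way optimum", {
  set.seed(14)
  for (rep in 1:8) {
    g <- randomConnectedGraph(sample(6:11, 1), 0.3)
    sp <- leadingEigenBisect(g)
    best <- enumerateBestBisection(g)
    expect_lte(sp$dQ, best$Q + 1e-9)
  }
})

test_that("recursive detection recovers bridged cliques and leaves K_n whole", {
  p <- detectCommunities(bridgedCliques())
  expect_equal(numCommunities(p), 2)
  mem <- communityMembership(p)
  expect_equal(length(unique(mem[letters[1:4]])), 1)
  expect_true(mem["a"] != mem["e"])
  expect_gte(partitionQ(p), 0)

  ig <- igraph::make_full_graph(6)
  igraph::V(ig)$name <- letters[1:6]
  expect_equal(numCommunities(detectCommunities(GeneGraph(ig))), 1)
  expect_error(detectCommunities(bridgedCliques(), maxK = 0), "maxK")
})

test_that("detected modularity is at least the trivial partition's and node permutation only relabels", {
  set.seed(15)
  g <- randomConnectedGraph(20, 0.15)
  p <- detectCommunities(g)
  expect_gte(partitionQ(p), 0)
  ## permute vertex ids and compare partitions as set families
  perm <- sample(numNodes(g))
  ig2 <- igraph::permute(asIgraph(g), perm)
  p2 <- detectCommunities(GeneGraph(ig2))
  split1 <- unname(lapply(split(names(communityMembership(p)),
                                communityMembership(p)), sort))
  split2 <- unname(lapply(split(names(communityMembership(p2)),
                                communityMembership(p2)), sort))
  expect_setequal(vapply(split1, paste, "", collapse = ","),
                  vapply(split2, paste, "", collapse = ","))
})

test_that("planted-partition graphs are recovered with high NMI", {
  net <- generateNetwork(syntheticConfig(), seed = 3)
  p <- detectCommunities(net$graph, maxK = 5)
  truth <- communityMembership(net$truePartition)[nodeNames(net$graph)]
  expect_gte(nmi(communityMembership(p)[nodeNames(net$graph)], truth), 0.9)
  ## our NMI agrees with the igraph implementation
  a <- communityMembership(p)[nodeNames(net$graph)]
  expect_equal(nmi(a, truth),
               igraph::compare(a + 1, truth + 1, method = "nmi"),
               tolerance = 1e-12)
})

test_that("target selection takes the top-FCI genes per community with deterministic ties", {
  fci <- setNames(c(5, 4, 3, 2, 1, 10, 9, 8), letters[1:8])
  zs <- matrix(0, 8, 10, dimnames = list(letters[1:8], GraphDTI:::.METRICS))
  fr <- new("FCIResult", zscores = zs, fci = fci, weights = fciWeights())
  mem <- setNames(c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L), letters[1:8])
  p <- new("Partition", membership = mem, Q = 0.1)
  ts <- selectTargets(fr, p, nTargets = 3)
  expect_equal(ts[["0"]], c("a", "b", "c"))
  expect_equal(ts[["1"]], c("f", "g", "h"))
  ## small community: all genes returned with a warning
  expect_warning(ts2 <- selectTargets(fr, p, nTargets = 5), "only 3")
  expect_equal(ts2[["1"]], c("f", "g", "h"))
  expect_lte(length(unlist(ts2)), 2 * 5)
  ## ties broken lexicographically
  fciT <- setNames(rep(1, 8), letters[1:8])
  frT <- new("FCIResult", zscores = zs, fci = fciT, weights = fciWeights())
  expect_equal(suppressWarnings(selectTargets(frT, p, 2))[["0"]], c("a", "b"))
})

test_that("cluster overrides force genes into the requested communities", {
  g <- bridgedCliques()
  p <- detectCommunities(g)
  ov <- data.frame(gene = "a", forced_cluster = communityMembership(p)[["e"]])
  p2 <- applyClusterOverride(p, ov, g)
  expect_equal(communityMembership(p2)[["a"]], communityMembership(p)[["e"]])
  expect_lt(partitionQ(p2), partitionQ(p))
  expect_error(applyClusterOverride(p, data.frame(gene = "zz", forced_cluster = 0)),
               "unknown gene")
})
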