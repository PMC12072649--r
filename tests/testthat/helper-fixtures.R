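## Small shared fixtures for the model-level tests.

pathGraph3 <- function() GeneGraph(cbind(c("a", "b"), c("b", "c")))

triangleGraph <- function() GeneGraph(cbind(c("a", "b", "c"), c("b", "c", "a")))

starGraph <- function(n = 6) {
  ig <- igraph::make_star(n, mode = "undirected", center = 1)
  igraph::V(ig)$name <- c("hub", sprintf("leaf%d", seq_len(n - 1)))
  GeneGraph(ig)
}

## a small connected graph + partition + model, cheap enough for
## gradient and contract tests
tinyModel <- function(dModel = 8, heads = 2, dropout = 0,
                      attnDropout = 0, seed = 7) {
  set.seed(41)
  g <- randomConnectedGraph(8, 0.5)
  mem <- setNames(rep(0:1, each = 4), nodeNames(g))
  part <- partition(mem, g)
  cfg <- dtiModelConfig(dModel = dModel, heads = heads, dropout = dropout,
                        attnDropout = attnDropout)
  model <- initDTIModel(g, part, nBits = 6, nDesc = 3, config = cfg,
                        seed = seed)
  list(graph = g, part = part, model = model)
}

tinyBatch <- function(B = 5, nBits = 6, nDesc = 3, seed = 3) {
  set.seed(seed)
  list(fp = matrix(rbinom(B * nBits, 1, 0.5), B, nBits),
       de = matrix(rnorm(B * nDesc), B, nDesc),
       geneIdx = sample(8, B, replace = TRUE),
       y = rbinom(B, 1, 0.5))
}
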