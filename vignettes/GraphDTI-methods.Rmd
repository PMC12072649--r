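---
title: "GraphDTI: methods and design notes"
author: "GraphDTI authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GraphDTI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

GraphDTI implements a network-medicine screening pipeline for disease
gene networks: topological prioritization of genes, spectral community
detection, and a multi-modal neural scorer of drug-gene interactions
with dual uncertainty quantification. This vignette explains the models,
the tunable parameters, the numerical choices, and what the synthetic
benchmark does and does not demonstrate.

## The Functional Centrality Index

Ten per-node metrics are computed on a connected, undirected, simple
gene interaction graph: degree, betweenness, closeness, local clustering
coefficient, neighborhood connectivity, radiality, eccentricity, average
shortest path length, stress, and the topological coefficient.
Betweenness and stress are unnormalized counts over unordered
source-target pairs, the convention of the standard network-analysis
desktop tools. Closeness is the reciprocal of the summed distances
`1 / sum_j d(i, j)`; radiality is
`sum_{j != i} (diam(G) + 1 - d(i, j)) / (n - 1)`; the topological
coefficient of a node `i` with degree `k_i > 1` averages
`(#shared neighbors + adjacency) / k_i` over all nodes sharing at least
one neighbor with `i`. Degenerate cases are defined explicitly:
clustering and topological coefficient of degree-0/1 nodes are 0, and a
disconnected input is an error (distance-based metrics are undefined
across components) that names the component sizes.

Each metric column is z-standardized (sample standard deviation). A
constant column carries no ranking information, so its z-scores are set
to 0 with a warning instead of failing on the division by zero. The
path-length-like metrics — average shortest path length, eccentricity
and stress — are multiplied by -1 after standardization so that larger
always means more central; stress is inverted deliberately even though
it is betweenness-like, following the source convention of the index.
The composite index is the weight-normalized sum
`FCI_i = (1/W) * sum_m w_m z_{m,i}`, invariant under positive rescaling
of the weights. No canonical weight vector exists for the index; the
package default up-weights betweenness (weight 2, all others 1) because
information-flow mediation is the property the index is meant to
capture, and every weight is configurable via `fciWeights()`.

`correlateFCI()` reports Pearson r with two-sided p-values of the index
against each raw metric — the standard companion diagnostic showing
which facets of topology the fused score tracks. Constant metrics give
`NA` (the correlation is undefined).

## Community detection

Communities are found by the leading-eigenvector modularity method: the
modularity matrix `B = A - k k' / (2m)` is built, the eigenvector of its
largest eigenvalue splits the graph by component signs (`v_i >= 0` maps
to +1), and splitting recurses on the *generalized* modularity matrix
`Bg = B[g, g] - diag(rowSums(B[g, g]))`, which keeps modularity gains
additive. A subset is indivisible when the leading eigenvalue is not
positive (tolerance 1e-9) or the split's modularity gain is at most
1e-12.

Plain sign splitting is known to land several percent of modularity
short of the optimum on noisy graphs, so each bisection is polished by
the classical vertex-moving fine-tuning stage: greedy single-vertex
flips, each vertex moved once per pass in order of gain, keeping the
best intermediate configuration, repeated while passes improve the
objective. On stochastic-block-model benchmarks (100 nodes, 5 planted
blocks, within/between edge probabilities 0.3/0.02) this lifts the
recovered partitions from normalized mutual information ≈ 0.7 to ≥ 0.9
against the planted labels; without it the spectral split alone
regularly merges adjacent blocks.

Recursion is greedy — among all current communities the split with the
largest positive gain is applied first — and stops at `maxK` or when no
gain remains; labels are relabeled by decreasing community size. The
eigenpair uses the dense symmetric solver up to 500 nodes and a shifted
power iteration (Gershgorin shift, deterministic start vector, tolerance
1e-9) above, so results carry no RNG dependence. Curated reassignment of
weakly-affiliated genes is supported as an explicit override table
(`applyClusterOverride()`), never hard-coded.

Per-community therapeutic targets are the `nTargets = 5` genes with the
highest FCI, ties broken lexicographically by gene id so target sets are
reproducible; communities smaller than the cap contribute all their
genes with a warning.

## Molecular representation

Each compound is represented two ways: a binary circular substructure
fingerprint (ECFP-type, radius 2, OR-folded to 2048 bits by default)
computed through the OpenBabel backend after SMILES canonicalization,
and a physicochemical descriptor vector (hydrogen-bond acceptor/donor
counts, logP, molar refractivity, molecular weight, fluorine count,
topological polar surface area) standardized column-wise against the
library's own moments. Constant descriptor columns map to zero.
Precomputed feature matrices are accepted everywhere, so the model is
agnostic to the descriptor panel; the bundled panel is intentionally
small and 2-D only (no conformer dependence). Unparsable structures are
skipped and reported, not fatal.

## The interaction model

The scorer is a multi-modal attention network operating on three
inputs: drug features, the gene graph, and the community assignment.

* **Molecular encoder** — fingerprint and descriptor pathways are
  two-layer perceptrons (leaky rectifier, slope 0.2; dropout 0.2; layer
  normalization), concatenated and projected to the shared embedding
  width `dModel`.
* **Gene encoder** — a learnable embedding per gene (Xavier-uniform
  initialization) passes two multi-head graph-attention layers
  (per-neighborhood softmax attention, 8 heads, concatenation
  aggregation, self-loops removed to avoid oversmoothing) and a
  width-restoring linear map, then one global multi-head self-attention
  (transformer) layer over the entire gene set for long-range context.
  The one-hot community vector is concatenated and projected back to
  `dModel` (517→512 at reference widths) with layer normalization and
  dropout.
* **Dual cross-attention** — for a (drug, gene) pair, queries from the
  drug attend over the gene representation and vice versa. Because each
  side of the pair is a single vector, a sequence-to-sequence reading
  would be degenerate (a softmax over one key). Each embedding is
  therefore treated as 8 head-tokens of the head dimension
  (`dk = dModel/8`; 64 at reference width, giving the documented scale
  `1/sqrt(dk) = 1/8`), which yields genuine 8×8 attention distributions
  per direction while keeping the printed projection shapes (512→512
  independent Q/K/V maps). Attention weights carry dropout 0.1.
* **Heads** — the fused `2*dModel` vector feeds a three-layer scorer
  (`2d → d → d/2 → 1`, leaky rectifier, layer norm, dropout) ending in a
  sigmoid (score `s` in [0, 1]) and an identically shaped aleatoric
  head. Two published descriptions of the aleatoric activation conflict
  (softplus vs a sigmoid scaled to a 0.5 ceiling); the bounded variant
  `u = 0.5 * sigmoid(·)` is the default because the screening threshold
  `tau = 0.5` presumes a bounded uncertainty, and softplus remains
  available via `uncertaintyActivation = "softplus"`.
* **Auxiliary heads** — a two-layer gene-classification head on the gene
  embeddings, and mirror-shaped two-layer decoders reconstructing the
  fingerprint and descriptor vectors from the molecular embedding.

The whole network — forward and analytic backpropagation — is
implemented in base R matrix code; every layer's gradient is validated
against central finite differences in the test suite, and a test
asserts that every named parameter receives a nonzero gradient (no dead
branch).

## Training objective and protocol

Three losses are combined: the uncertainty-weighted interaction loss
`sum BCE(s, y)/u + 0.1 * sum log u` (confident errors amplified, blanket
uncertainty penalized; `u` clamped at 1e-6 because the bounded head can
approach zero), the gene-classification BCE, and a molecular
reconstruction loss. Two reconstruction variants exist — elementwise
BCE + MSE (default, matching the implementation-level description of
the protocol) and an L1 + squared-L2 norm variant — selected by
`reconVariant`. The gene and reconstruction weights have no published
values; both default to 1.

Optimization follows the reference protocol exactly: Adam (β1 = 0.9,
β2 = 0.999), learning rate 1e-4, batch size 64, L2 weight decay 1e-5,
early stopping on validation AUROC with patience 10, pair-level
70/10/20 label-stratified splits, and an optional self-supervised
reconstruction warm-up on the drug library weighted 0.3. Training
minimizes the batch mean of the summed objective (scale-equivalent per
batch). Evaluation uses the 0.5 decision threshold for
precision/recall/F1 and the rank (Mann-Whitney) statistic for AUROC.

Monte-Carlo-dropout inference keeps all dropout layers active for
`T = 10` stochastic passes and reports the mean score, the population
variance across passes (epistemic uncertainty) and the mean aleatoric
output, reproducible under a seed.

## Screening, ranking, multi-target extraction

Libraries are screened in drug batches of 64. Post-hoc normalization is
computed per target gene: the z-score of the mean score against the
screened library (population standard deviation) and the empirical rank
percentile `100 * (N - rank_index)/N` (best record = 100), deliberately
rank-based rather than normal-theory based. The uncertainty filter keeps
records whose total uncertainty — aleatoric plus the MC standard
deviation, capped at 1 — is below `tau = 0.5`, relaxing once to 0.7 if
fewer than 10 distinct drugs survive. Ranking aggregates over the
target set: mean score minus `lambdaPenalty` times the mean per-pair
`sqrt(u^2 + sigma^2)`; the radical covers both uncertainty components
so they combine on a common scale, and the penalty weight is a separate
parameter (default 1) rather than overloading the reconstruction
weight's symbol. Multi-target candidates must exceed z = 2.8 for at
least two target genes in at least two distinct communities — the
defining signature of network-spanning polypharmacology — and are
reported with the best gene per cluster, mean z, percentile, mean
probability (100·s̄) and mean total uncertainty.

## The synthetic benchmark

The generator produces the conditions every end-to-end test runs under:
a stochastic-block-model gene network (100 genes, 5 blocks, edge
probabilities 0.3 within / 0.02 between; largest component retained), a
200-drug library, and labeled interactions with a calibrated 10%
positive rate. Drugs and genes carry latent pharmacology vectors
(dimension 8): gene latents sit near their cluster centroid (noise 0.3),
25% of drugs align with a random centroid (noise 0.5), the rest are
isotropic background compounds with reduced latent norm, and one
planted drug aligns with two centroids at once — the ground-truth
polypharmacology candidate. Fingerprint bits are Bernoulli draws whose
probabilities are logistic in the latent, and descriptors are a linear
map of the latent plus Gaussian noise, so observable features are
informative of pharmacology the way real fingerprints and descriptors
are. Interaction labels are `Bernoulli(sigmoid(alpha <z_d, z_g> +
beta))` with `alpha = 12` — the single difficulty knob, fixed so the
Bayes-optimal AUROC of the task is ≈ 0.95, i.e. clearly separable but
not trivial — and `beta` calibrated by root finding to the target
positive rate. Labeled pairs sample 40 genes per drug (~8,000 pairs —
about 80 labeled pairs per gene, enough signal for the per-gene
embeddings to be learnable — leaving a held-out test split of ~1,600
pairs at the 70/10/20 fractions).

What passing on this benchmark shows: the implementation can detect the
planted community structure, learn a genuinely separable multi-modal
signal to AUROC ≥ 0.85 under the reference protocol, quantify
uncertainty consistently, and surface a planted multi-target compound
through the full screen→normalize→filter→rank path. What it does not
show: performance on real interactomes or chemical space — the
generator matches none of the degree heterogeneity, chemical redundancy
or label noise of curated drug-target data, so benchmark metrics must
not be read as estimates of real-data performance.

Benchmark-scale runs in the tests and the acceptance script use a
96-wide model (8 heads) rather than the 512-wide reference
configuration; widths are configurable and the architecture is
identical, the narrower setting being the package's chosen desk-scale
problem size. A full benchmark training run takes a few minutes on one
CPU.

## Numerical choices and limitations

* Eigen tolerance 1e-9, modularity-gain floor 1e-12; eigenvector sign
  ties (`v_i = 0`) assign to +1.
* Softmax stabilization subtracts the running maximum; attention rows
  always sum to 1 within 1e-6.
* Layer normalization uses eps 1e-5; scores are clamped to
  (1e-12, 1 - 1e-12) inside BCE.
* Percentile ties and ranking ties break deterministically (score, then
  total uncertainty, then drug id).
* All randomness flows through explicit seeds; training on one CPU
  thread is bit-reproducible, while multi-threaded BLAS may reorder
  floating-point sums and perturb long training trajectories.
* The screening stage holds all pair records in memory; libraries
  beyond ~10^6 (drug, target) pairs would need chunked screening.
* The CLI (`inst/cli/graphdti.R`) is a thin wrapper over the exported
  functions; all functionality is available programmatically.
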