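# GraphDTI

Network-based drug repurposing for disease gene networks, in R.

Complex diseases rarely hinge on one gene: risk loci form interaction
networks whose topology identifies the genes worth drugging and whose
modular structure separates distinct pathological mechanisms. GraphDTI
is for computational biologists and cheminformaticians who want to go
from an interaction network and a compound library to a ranked,
uncertainty-aware list of drug–gene interaction candidates — including
*multi-target* (polypharmacology) compounds that act on several disease
modules at once.

The pipeline has three stages:

1. **Topology — the Functional Centrality Index (FCI).** Ten per-node
   metrics (degree `k_i`, betweenness `C_B`, closeness `C_C`, clustering
   `C_i`, neighborhood connectivity, radiality, eccentricity `ε_i`,
   average shortest path length `L_i`, stress `S_i`, topological
   coefficient `T_i`) are z-standardized, the path-length-like metrics
   (`L_i`, `ε_i`, `S_i`) sign-inverted, and fused:

   `FCI_i = (1/W) Σ_m w_m · z_{m,i}`, `W = Σ_m w_m`

   Betweenness is up-weighted by default (w = 2); all weights are
   configurable.

2. **Communities.** Leading-eigenvector modularity optimization: split
   by the sign pattern of the dominant eigenvector of the modularity
   matrix `B_ij = A_ij − k_i k_j / 2m`, polish each split with the
   classical vertex-moving refinement, and recurse on the generalized
   modularity matrix while the gain `ΔQ = s'Bs/4m` is positive. The
   top-5 FCI genes per community become the screening targets.

3. **Interaction model and screening.** A multi-modal attention network
   scores drug–gene pairs: a two-pathway molecular encoder (2048-bit
   circular fingerprints + physicochemical descriptors), a
   cluster-aware gene encoder (two 8-head graph-attention layers, a
   global transformer layer, cluster one-hot projection), dual
   cross-attention fusion, and twin heads emitting the score
   `s ∈ [0,1]` and a bounded aleatoric uncertainty `u ∈ [0, 0.5]`.
   Training minimizes `L_DTI + L_gene + L_recon` with
   `L_DTI = Σ BCE(s,y)/u + 0.1·Σ log u` (Adam, lr 1e-4, batch 64,
   weight decay 1e-5, early stopping on validation AUROC, patience 10).
   Screening runs 10 Monte-Carlo-dropout passes per pair (epistemic
   variance σ²), z-normalizes scores per target gene, filters at total
   uncertainty τ = 0.5 (relaxed to 0.7 if < 10 drugs survive), and
   ranks drugs by

   `Rank(d) = mean_g s̄ − λ · mean_g √(u² + σ²)`

   Multi-target candidates are drugs with z > 2.8 for ≥ 2 target genes
   in ≥ 2 distinct communities.

The whole network, including analytic backpropagation, is implemented
in base R matrix code and validated against finite differences in the
test suite. A synthetic-data module generates planted-community
networks, feature-informative drug libraries, and calibrated
interaction labels (10% positives) with one planted polypharmacology
drug, so the entire pipeline is testable offline.

## Worked example

```r
library(GraphDTI)

## synthetic benchmark: 100 genes in 5 planted clusters, 200 drugs,
## ~8,000 labeled pairs at a calibrated 10% positive rate
bench <- generateBenchmark(syntheticConfig(), seed = 1)

part <- detectCommunities(bench$graph, maxK = 5)
part
#> Partition: 100 nodes in 5 communities (Q = 0.5951)
#>   sizes: 20, 20, 20, 20, 20

ct  <- computeCentralities(bench$graph)
fci <- computeFCI(ct)
head(correlateFCI(fci, ct), 3)
#>        metric         r            p
#> 1      degree 0.8049694 6.014047e-24
#> 2 betweenness 0.7174589 4.548291e-17
#> 3   closeness 0.9187308 2.484764e-41

inter <- splitDataset(bench$interactions, seed = 1)
model <- initDTIModel(bench$graph, part, nBits = 128, nDesc = 16,
                      dtiModelConfig(dModel = 96, heads = 8), seed = 1)
model <- trainDTIModel(model, bench$lib, inter, bench$geneLabels,
                       dtiTrainConfig(maxEpochs = 60, seed = 1,
                                      pretrainEpochs = 2))
evaluateModel(model, bench$lib, inter, "test")
#> $auroc      0.860   $precision  0.645
#> $recall     0.263   $f1         0.374   (n = 1600 held-out pairs)

targets <- selectTargets(fci, part, nTargets = 5)
rec <- normalizeScores(screenLibrary(model, bench$lib, targets, seed = 1))
rankDrugs(rec, unlist(targets), lambdaPenalty = 1)[1:3, ]
#>   drug_id  affinity totalUncertainty  rankScore rank
#> 1   D0023 0.3088200        0.5149457 -0.2061256    1
#> 2    D_MT 0.2903521        0.5140968 -0.2237447    2
#> 3   D0013 0.2689913        0.5121561 -0.2431648    3
findMultitarget(rec, zThreshold = 2.8)
#>   drug_id   targets  z_score percentile probability_pct uncertainty
#> 2    D_MT g014;g024 4.492798      99.50        66.79939   0.6484428
#> 1   D0037 g061;g100 3.586256      98.75        54.85646   0.6589365
```

`detectCommunities()` recovers the five planted blocks exactly on this
seed (modularity Q ≈ 0.60, normalized mutual information 1.0 against
the planted labels); the FCI correlates most strongly with closeness
(r = 0.92) and degree (r = 0.80), as a centrality composite should.
Training reaches a held-out AUROC of 0.86 on this separable benchmark
(Bayes optimum ≈ 0.95), and the planted multi-target drug `D_MT` is the
top multi-target extraction (mean z = 4.49 across two clusters) and
ranks 2nd of 200 in the penalized ranking.

A thin command-line wrapper over these functions is included:

```sh
Rscript inst/cli/graphdti.R simulate --seed 1 --out fixtures/
Rscript inst/cli/graphdti.R cluster --network fixtures/network.tsv --max-k 5 --out clusters.tsv
Rscript inst/cli/graphdti.R centrality --network fixtures/network.tsv --out centrality.tsv
```

See `vignettes/GraphDTI-methods.Rmd` for the models, parameter
defaults, numerical choices and the benchmark's scope and limits.

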