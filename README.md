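# corsignet

Correlation-weighted signaling-network analysis of tumor versus normal
cohorts.

Malignant cells rewire how signals travel from membrane receptors to
transcription factors. `corsignet` quantifies that rewiring from ordinary
cohort expression data and a protein–protein interaction network: it is
aimed at computational biologists who have gene-level expression matrices
for a tumor cohort and a matched normal cohort and want comparable,
network-level regulation statistics for the two.

## The method

Every interaction between genes *x* and *y* is weighted per cohort by the
Pearson correlation of their expression over the *n* samples, and turned
into a **link distance**

> ρ<sub>xy</sub> = Σ(xᵢ−x̄)(yᵢ−ȳ) / √(Σ(xᵢ−x̄)² Σ(yᵢ−ȳ)²),  d<sub>xy</sub> = 1 − |ρ<sub>xy</sub>|

so strongly co-regulated neighbours are close. A **pathway** is the
Dijkstra shortest path from a receptor to a transcription factor over
these distances; one is computed for every (receptor, TF) pair, with a
deterministic tie rule (fewest hops, then lexicographically smallest node
sequence). Links and nodes on no pathway are removed and the largest
connected component becomes the cohort's **signaling network**.

On that network the package computes a feature panel — link/node usage
frequencies (a restricted betweenness), mean pathway length in hops,
Shannon entropy *I* = −Σ pᵢ log₂ pᵢ of pathway traffic over links,
clustering coefficients *C* = 2L/(k(k−1)), the power-law exponent α of
the link-frequency distribution (continuous MLE of the
cumulative-distribution method), average diameter, and the diameter
increase after removing the top 10% of hubs — plus three motif counters
comparing the cohorts around cancer-mutated hubs (integration,
maintenance, and the comparative receptor-pair motif). A cross-dataset
stage applies paired Wilcoxon signed-rank tests (exact enumeration when
tie-free, tie-corrected normal approximation otherwise) and Fisher
enrichment tests.

A seeded synthetic-study generator (scale-free network, Gaussian
propagation along a spanning tree, tumor regime obtained by attenuating
edge correlations) lets the whole pipeline run with no external
downloads. See `vignettes/corsignet-methods.Rmd` for the full model
description and design choices.

## Worked example

```r
library(corsignet)

study <- generatePairedCohorts(nNodes = 120, nReceptors = 10, nTfs = 8,
                               nSamples = 80, lambda = 0.3, seed = 42)
analyse <- function(expr) {
  net <- buildWeightedNetwork(study$interactions, expr)
  buildSignalingNetwork(net, extractPathways(net, study$receptors, study$tfs))
}
snN <- analyse(study$normal); snT <- analyse(study$tumor)
snN
#> SignalingNetwork: 31/120 nodes, 41/237 links used by 80 pathways

out <- rbind(normal = networkFeatures(snN), tumor = networkFeatures(snT))
round(out[, c("n_links", "n_nodes", "path_length", "entropy",
              "link_distance", "clustering")], 3)
#>        n_links n_nodes path_length entropy link_distance clustering
#> normal      41      31       3.575   4.872         0.463      0.013
#> tumor       58      38       3.087   5.599         0.843      0.016
```

With the tumor cohort's correlations attenuated (λ = 0.3), its link
distances rise (0.843 vs 0.463), pathway traffic disperses over more
links (higher entropy, more links and nodes used), and pathways shorten
in hops — the directional signature the feature panel is designed to
detect.

The cross-dataset stage consumes a per-dataset feature table; the bundled
panel of twenty tumor/normal cohort pairs is a ready-made input:

```r
cmp <- compareFeatures(cohortFeaturePanel())
cmp[cmp$feature %in% c("n_links", "entropy", "comparative_motif"),
    c("feature", "meanNormal", "meanTumor", "tendency", "pValue")]
#>              feature meanNormal meanTumor tendency    pValue
#> 4  comparative_motif  2.942e+07 1.570e+07     Down 9.537e-06
#> 6            entropy  1.144e+01 1.202e+01       Up 4.164e-04
#> 11           n_links  1.681e+04 1.915e+04       Up 3.815e-06
```

Tumor networks use more links, carry higher entropy, and lose the
comparative motif (pathway pairs sharing links in normal but not tumor
tissue), each with a paired signed-rank p-value across the twenty pairs.

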