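---
title: "Correlation-weighted signaling networks: model and methods"
author: "corsignet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-weighted signaling networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corsignet)
```

# The model

Signal transduction is modelled on an undirected protein--protein
interaction network in which proteins are represented by their coding
genes.  Given a cohort of expression profiles (genes x samples, assumed
gene-level and pre-normalized), every interaction between genes $x$ and $y$
is weighted by the Pearson correlation of their expression across the $n$
samples,

$$\rho_{xy} = \frac{\sum_{i=1}^n (x_i-\bar x)(y_i-\bar y)}
  {\sqrt{\sum_i (x_i-\bar x)^2 \sum_i (y_i-\bar y)^2}},
  \qquad d_{xy} = 1 - |\rho_{xy}|.$$

The absolute value treats induction and inhibition alike: what matters is
co-regulation, not its sign.  Strongly co-regulated neighbours are *close*
($d \to 0$), uncorrelated ones *far* ($d \to 1$).  Correlations are
computed per cohort, so a tumor and its matched normal cohort share the
same topology but carry different weights.

A *pathway* is the single minimum-distance route from a receptor to a
transcription factor (Dijkstra's algorithm over $d_{xy}$), computed for
every ordered (receptor, TF) pair.  Links and nodes on no pathway are
removed and the analysis continues on the largest connected component of
the remainder -- the *signaling network*.  The number of pathways passing
through a link (its *link frequency*) is a restricted betweenness: only
receptor-to-TF shortest paths are counted, not all node pairs.

On the signaling network the package computes, per cohort: link/node
counts and usage frequencies, mean pathway length in hops, the Shannon
entropy of pathway traffic
$I = -\sum_i p_i \log_2 p_i$ with $p_i$ proportional to link frequency,
local clustering coefficients, the power-law exponent $\alpha$ of the
link-frequency distribution ($P(f) \sim f^{-\alpha}$), the average network
diameter, and the diameter increase after removing the top 10% of hubs.
Three motif counters compare the cohorts directly (below), and the
cross-dataset stage applies paired Wilcoxon signed-rank tests to each
feature over many dataset pairs.

# Numerical and design choices

**Clustering coefficient.** For a node with $k$ neighbours and $L$ links
among them we use $C = 2L/(k(k-1))$, which is 1 for a fully connected
neighbourhood and 0 for an unconnected one; the unnormalized ratio
$L/(k(k-1))$ could never reach 1 on an undirected graph.  Nodes with
$k < 2$ get $C = 0$ (the ratio is undefined there).

**Path length versus diameter.** Pathway length is reported as the hop
count of the distance-optimal path (weighted optimality decides *which*
path; hops measure *how long* it is -- cascade depth is the biologically
interpretable number).  The average diameter uses the pure hop metric over
all node pairs, matching the convention of the robustness literature the
hub-removal measure comes from.  Unreachable pairs are excluded from the
diameter mean rather than penalized, because any finite penalty would be
arbitrary; after hub removal the diameter is taken on the largest
remaining component for the same reason.

**Tie rule for shortest paths.** Among equal-distance optima the search
prefers fewer hops, then the lexicographically smallest node sequence.
Usage frequencies, and therefore hubs and motif counts, depend on which
optimum is reported, so the choice must be deterministic; this particular
rule is also cheap to implement exactly (greedy reconstruction against a
Dijkstra tree rooted at the target).  Equality of path distances is judged
at $10^{-9}$ to absorb floating-point drift in summed weights.

**Undefined correlations.** A zero-variance gene makes $\rho$ undefined.
Such links are kept with $\rho = \mathrm{NA}$ and the maximal distance 1
rather than deleted: the graph stays intact, while Dijkstra avoids the
link unless it is the only route.  Their category is `none`.

**Correlation categories.** $|\rho| \in [0, 0.3)$ is `none`, $[0.3, 0.5]$
is `low`, $(0.5, 1]$ is `high`.  The interval bounds follow the published
convention ("high" is *above* 0.5); placing both boundary points in `low`
makes the ties deterministic.

**Power-law exponent.** The continuous maximum-likelihood form
$\hat\alpha = 1 + n\,[\sum_i \ln(f_i/f_{\min})]^{-1}$ of the
cumulative-distribution method is the default; it avoids binning noise in
the tail.  A discrete half-step variant ($f_{\min}-0.5$) is available
behind an argument.  The least-squares intercept offered alongside is for
log--log plotting only and never feeds the estimate.

**Motif definitions.** Triangles are enumerated around *cancer-mutated
hubs*: the cancer-gene list intersected with nodes present in both
cohorts' networks, ranked by node frequency per cohort, top-$k$ ($k = 50$
by default) per cohort, union.  Only triangles whose three links exist in
*both* signaling networks are counted, which keeps the normal and tumor
counts comparable.  The *integration* motif requires all three links
`high` in the counted cohort.  The *maintenance* motif requires both hub
links `high` in one cohort and `none` in the other while the
neighbour--neighbour link keeps its category; the count is attributed to
the cohort in which the hub is *de-correlated*, since the motif describes
hub detachment.  The *comparative* motif is restricted to receptor pairs
converging on the same transcription factor -- the configuration the motif
was designed around; arbitrary pathway pairs would conflate different
signal-integration events.  Pathway pairs share when they have at least
one common undirected *link*; common nodes alone do not count.

**Wilcoxon signed-rank statistics.** Differences $d$ = tumor $-$ normal;
zeros are dropped; $|d|$ is midranked; $W^+$ is the rank sum of positive
differences.  In `auto` mode the exact two-sided tail (computed by the
generating-function recursion, equivalent to enumerating all $2^n$ sign
assignments) is used when the nonzero $|d|$ are tie-free, otherwise the
normal approximation with continuity correction $0.5$ and tie-corrected
variance $n(n+1)(2n+1)/24 - \sum(t^3-t)/48$.  `exact` mode forces the
integer-rank exact tail with deterministic tie-breaking; it is valid when
tied $|d|$ do not mix signs, the situation that arises when ties are an
artifact of *rounded* input values (as in a printed feature table), and it
then recovers the statistic of the unrounded data.  Two-sided
$p = \min(1,\, 2\min(\text{lower},\text{upper}))$.  No multiple-testing
correction is applied; the comparison stage reports raw $p$ per feature.

**Stratification.** Unequal cohorts are balanced by deleting random
samples of the larger cohort (uniform, without replacement, seeded).
Features such as correlation estimates are sample-size dependent, so the
two cohorts of a pair must be compared at equal $n$.

**Expression input.** Duplicate gene rows are a hard error, not silently
aggregated: probe-to-gene reduction is upstream of this package and
silent averaging would mask mapping mistakes.  Missing values are a hard
error for the same reason.  Symbols are matched case-sensitively after
whitespace trimming.

# The synthetic-data generator

`generatePairedCohorts()` builds a study that exercises every stage
without external data:

* a Barabasi--Albert preferential-attachment network (default 300 nodes,
  $m = 2$) -- connected and heavy-tailed, the regime in which hub-centred
  statistics are meaningful;
* disjoint receptor and TF sets sampled uniformly (defaults 20 and 15 --
  roughly the receptor/TF proportion of the real networks at this scale);
* target absolute correlations per link drawn from a configurable law,
  default $\mathrm{Beta}(4, 2)$ (mean $2/3$, i.e. mean link distance
  $\approx 0.33$, the strong co-regulation of normal tissue);
* two cohorts of 200 samples each, simulated by Gaussian propagation
  along a breadth-first spanning tree: the root gene is standard normal
  and each child is $\rho\,\mathrm{parent} + \sqrt{1-\rho^2}\,
  \varepsilon$.  The tumor cohort uses the same targets multiplied by an
  attenuation $\lambda \in [0,1]$ (default 0.3), emulating the weaker
  co-regulation of malignant tissue; $\lambda = 1$ gives identically
  distributed cohorts.

Correlations are imposed only on a spanning tree because an arbitrary
edge-wise assignment on a cyclic graph need not be positive definite;
non-tree-edge correlations emerge from the tree paths (the product of the
edge targets along the connecting path) and are measured, not asserted.
Attenuation multiplies the targets rather than adding noise so they stay
in $[0,1]$ by construction.

What the generator does *not* emulate: microarray noise models, batch
effects, probe-level artifacts, non-Gaussian marginals, or biologically
structured role placement.  Passing the synthetic-recovery checks
therefore demonstrates that the *pipeline* transforms a known
correlation contrast into the expected feature contrast (larger link
distances, higher entropy, weaker dominant links, shorter hop paths in
the attenuated cohort); it does not validate the biological conclusions
on real tissue.

# Problem sizes and determinism

The test-suite and acceptance runs use deliberately modest sizes -- random
graphs of up to 50 nodes for the brute-force motif cross-checks, 300-node
networks with 200 samples per cohort for the synthetic recovery run,
$5\times10^4$ draws for the exponent-estimator check -- chosen so the
exhaustive oracles (all simple paths, all $2^n$ sign assignments, all node
triples) remain feasible while the statistics are stable.  Every random
step takes an explicit integer seed, and identical configuration plus seed
reproduces byte-identical reports.

# Known limitations

* The tie rule selects one canonical shortest path; a different rule
  would shift usage frequencies and motif counts on graphs with many
  degenerate optima (near-uniform weights).  All counts are therefore
  defined *relative to the documented rule*.
* Cohort-level correlation networks say nothing about single samples; the
  method compares cohorts, it does not diagnose patients.
* The comparative-motif count is restricted to same-TF receptor pairs
  and grows quadratically in receptors per TF; the implementation uses an
  incidence cross-product per TF, which is exact but assumes the pathway
  sets fit in memory.
* The bundled cross-dataset feature panel stores values at the precision
  they were published at; statistics that are sensitive to sub-rounding
  differences (notably tie structure in small columns) can differ from
  statistics computed on unrounded values.  The `exact` Wilcoxon mode
  exists precisely for that situation, and the remaining discrepancies
  are documented rather than resolved.
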