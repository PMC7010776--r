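---
title: "Flow centrality: model, nulls and design choices"
author: "flowCentral"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow centrality: model, nulls and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowCentral)
```

## The problem

Two related diseases — think of two chronic respiratory disorders with
overlapping symptoms but largely disjoint GWAS hits — may interact through
genes that belong to neither disease's core module. On a protein–protein
interaction network, such mediators should sit on the communication routes
*between* the two disease neighborhoods. Classic betweenness centrality
cannot find them: it averages over all node pairs and therefore ranks the
same global hubs regardless of which diseases are being compared.

`flowCentral` implements a module-to-module betweenness, **flow
centrality**, together with the full statistical machinery needed to decide
whether the genes it highlights are biologically coherent: disease-module
construction, a degree-preserved null for the centrality, selection of
flow-central network paths, two null path ensembles, and path-level
ontology-similarity and coexpression statistics.

## The measure and its null

For a source gene set $S$ and target gene set $T$ on an undirected, simple,
connected interactome,
$$\mathrm{FC}^{S,T}(v) \;=\; \frac{1}{|S||T|} \sum_{s \in S,\, t \in T}
\frac{\sigma_{st}(v)}{\sigma_{st}},$$
where $\sigma_{st}$ counts shortest $s$–$t$ paths and $\sigma_{st}(v)$
those passing *strictly through* $v$.

Three conventions the formula leaves open, and how this package resolves
them:

* **Endpoints.** A pair never contributes to its own endpoints
  ($\sigma_{st}(v) = 0$ for $v \in \{s, t\}$). This is what makes the
  $S = T = V$ limit coincide with endpoint-excluding Freeman betweenness
  (ordered pairs: $\mathrm{FC} \cdot |V|^2 = 2 \cdot$ the usual undirected
  betweenness), a reduction the test suite asserts node-for-node.
* **Overlapping modules.** Pairs with $s = t$ contribute 0 while the
  normalization keeps the full $|S||T|$ product; overlap therefore deflates
  all values by the same factor and cannot reorder nodes.
* **Computation.** Values come from breadth-first predecessor-DAG
  accumulation restricted to the $S \times T$ pairs (a Brandes-style pass
  per source, implemented in C++), never from path enumeration. An
  exhaustive-enumeration oracle on small random graphs checks exactness to
  1e-12.

Raw flow centrality is hub-biased, so significance is assessed against a
null of randomized module pairs. The **flow centrality score** is the
per-node z-score
$$\mathrm{FCS}(v) = \frac{\mathrm{FC}(v) - \mu_{FC}(v)}{\sigma_{FC}(v)},$$
with $\mu_{FC}, \sigma_{FC}$ the mean and (sample) standard deviation of
the node's flow centrality across `nSamples` random module pairs (1000 by
default), complemented by a right-tailed empirical p-value with the
plus-one correction $(1 + \#\{null \ge obs\})/(1 + n)$. The phrase "mean
and standard deviation across the samples" admits a pooled reading
(moments taken over all nodes and samples jointly); we implement the
per-node reading as the statistically sensible one — a pooled null would
compare every node against a single global scale and reintroduce the
degree bias the randomization is meant to remove — and expose the pooled
variant behind `pooledNull = TRUE` for comparison. When a node's null
standard deviation is zero, its FCS is 0 if the observed value matches the
null mean and a signed `Inf` sentinel otherwise; consumers fall back on
the empirical p-value, so the ranking stays well defined without dividing
by zero.

## Module construction and randomization

Disease modules are grown by iterative connectivity significance (the
DIAMOnD scheme): at each step every node adjacent to the module is scored
with the hypergeometric tail probability of showing at least its observed
number of links into a module of the current size, and the smallest
p-value wins. Ties are resolved deterministically — lowest p, then highest
module connectivity, then lowest degree, then lexicographic identifier —
so module content is reproducible. Seed weighting is deliberately not
implemented. The iteration cutoff is chosen by scanning the enrichment of
a reference gene set (e.g. GWAS-significant genes, pre-filtered to exclude
the seeds) among the added genes and taking the curve's minimum, with the
universe being the network minus the seeds.

Null modules must look like real modules. Simply drawing degree-matched
genes produces scattered sets that are topologically nothing like a
DIAMOnD module, so the z-score would conflate compactness with signal. The
`"diamond"` randomization therefore replaces each *seed* with a
degree-matched draw and re-expands the random seeds to the original module
size. When a module is a flat association gene set (no expansion step),
the `"degree_only"` mode resamples the whole set degree-preserved.

Degree matching uses contiguous degree bins of at least `minBinSize` nodes
(default 20). Exact-degree matching is available via `minBinSize = 1`;
exhausted bins (e.g. singleton hub classes) fall back to the nearest
neighbouring bin with a warning. Bin occupancy, not exact degree, is the
sampling unit because high-degree classes are singletons in any real
interactome and exact matching would make sampling without replacement
impossible.

## Paths and their nulls

Flow-central paths are shortest paths between the two seed sets whose
every intermediate gene has $\mathrm{FCS} > 2$ and participates in at
least five source–target geodesics (the support filter removes nodes whose
scores rest on too few paths to be stable). Two points the threshold
leaves open: the inequality is implemented strictly (`> 2`), with an
inclusive mode available, since the describing texts alternate between
"greater than 2" and "2 or greater"; and paths with no intermediates carry
no mediator information, so 2-gene paths are dropped. Duplicate gene
sequences are removed. A relaxed mode (`fcs > 2` *or* empirical
$p < 0.05$) is available for sensitivity-maximizing searches anchored at a
single source gene. Geodesics are enumerated from the BFS predecessor DAG
with a deterministic lexicographic expansion order and a per-pair cap
(default 1000) that is logged whenever it binds.

Two null ensembles calibrate path-level statistics:

* **Type A (length-preserved):** a path length is drawn from the empirical
  flow-central length distribution, then realized as a uniform
  self-avoiding walk from a uniform start node. Dead ends restart the
  whole walk rather than backtracking — backtracking would bias step
  probabilities — and after 100 failed walks the length is re-drawn.
* **Type B (endpoint-preserved):** uniform draws *with replacement* from
  the seed-to-seed geodesic pool. With replacement because the pool of
  distinct central paths is typically far smaller than the 10,000 draws
  used for the null.

## Path-level statistics

**Sequential similarity (SS)** of a path $(g_1, \ldots, g_n)$ is the mean
best-match-average Resnik similarity of adjacent genes. Conventions: the
information content is $-\log$ (natural base) of a term's
ancestor-propagated annotation frequency, normalized per namespace root so
every root has IC exactly 0 — any other base rescales all similarities
jointly and cannot change rank-based comparisons; the best-match sums run
over *direct* annotation sets while the common-ancestor search uses the
propagated hierarchy (the standard Resnik/BMA construction); pairs
involving an unannotated gene contribute 0 and are flagged, with a strict
mode that drops such paths entirely. All namespaces are pooled by default;
a per-namespace run reproduces the cellular-component / molecular-function
/ biological-process split.

**Sequential coexpression (SC)** is the mean absolute Pearson correlation
of adjacent genes, maximized over all probe pairs mapping to the two genes
(many-probes-per-gene data). A path containing a gene absent from the
expression matrix is null and excluded; genes whose probes all have zero
variance in the analyzed sample class are treated the same way (identical
information state). Disease and control classes are always analyzed
separately, and a dataset is summarized by its least significant class.

Both statistics are compared against Type A and Type B with right-sided
Mann–Whitney tests (exact U distribution for tie-free samples up to
combined size 20, tie-corrected normal approximation otherwise), and a
comparison is summarized by its **worst case**, the maximum of the two
p-values, reported as $-\log_{10} p$.

## The synthetic study

Because the real inputs (proprietary interactome snapshots, GWAS
repositories, expression archives) cannot ship with a package, every claim
is validated on seeded generators whose planted structure makes the
expected outcome known:

* **Planted-bridge graphs** — two Erdős–Rényi modules (60 nodes each,
  within-module edge probability 0.15), a sparse background (200 nodes,
  edge probability 0.02) attached to the source module only, and 3 bridge
  nodes carrying *all* inter-module connections (8 edges into each
  module). A degree-matched control hub wired only into the source module
  provides the specificity contrast. Seeds are random 10-gene subsets of
  each module. Sizes were chosen so a full study replicate (200-sample
  FCS, geodesic enumeration, two 200-path nulls) runs in seconds;
  connectivity is enforced by rejection sampling (≤ 50 retries) rather
  than edge augmentation so the degree structure is not biased.
* **Synthetic ontologies** — a random layered rooted DAG (60 terms, depth
  4); background genes get 3 random non-leaf annotations; each planted
  path is assigned one deepest-layer term annotated to all its genes, so
  adjacent planted genes share a high-IC term.
* **Latent-factor expression** — planted genes follow
  $x_g = \lambda f + \sqrt{1-\lambda^2}\,\sigma\,\varepsilon$ with a
  single shared factor $f$ (default $\lambda = 0.7$, $\sigma = 1$, 40
  samples split into disease/control), background genes are pure noise,
  and each gene is emitted as 2 probes with independent probe noise of sd
  $0.25\sigma$. At $\lambda = 1, \sigma = 0$ planted coexpression is
  exactly 1; at $\lambda = 0$ planted and background genes are
  indistinguishable.

What passing these tests does **not** show: the generators use
Erdős–Rényi topology (no scale-free degree tail), clean annotations, and
Gaussian expression — real interactomes, ontology corpora and expression
archives are messier in all three respects, and results there inherit the
biases of the underlying data.

## Numerical choices and degenerate inputs

* Empirical p-values always use the plus-one convention, so they live in
  $[1/(1+n), 1]$ and are never zero.
* Hypergeometric tails are computed by `phyper`; the suite checks them
  against direct combinatorial summation over a full grid up to $N = 50$
  at 1e-12.
* Gene identifiers are opaque strings; symbol/identifier mapping is a
  user-side preprocessing concern.
* Modules that exhaust their boundary stop early with a warning rather
  than failing, so small synthetic graphs behave.
* All stochastic operations take an explicit integer seed and reruns are
  bit-identical; the pipeline writes every derived stage seed into its
  manifest.

## Known limitations

* **Within-pool dependence.** Paths in a geodesic pool share genes — in
  the planted fixture, *every* inter-module geodesic crosses the bridge
  nodes — so their SS/SC values are not independent samples. The
  Mann–Whitney comparison is exactly calibrated for independent path
  groups (verified: for independent self-avoiding-walk pools under
  unstructured annotations or white-noise expression, the p-value is
  uniform), but for strongly overlapping pools the rank-sum variance is
  inflated and null p-values are overdispersed (too many extreme values
  in both tails). Separation calls on planted structure are far beyond
  this inflation, but marginal p-values on heavily overlapping pools
  should be read with care.
* The per-pair geodesic cap can truncate path pools on very dense graphs;
  it is logged whenever it binds.
* Weighted or directed interactions, random-walk/communicability
  betweenness variants, and alternative semantic similarity families
  (Lin, Wang) are out of scope.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the synthetic study at the
default generator sizes above, with 200-sample FCS nulls, 200-path null
ensembles and 50 (suite) or 10 (acceptance script) study replicates;
oracle comparisons use 100 random graphs of up to 12 nodes, 20 graphs for
the betweenness reduction, and the full hypergeometric grid up to
$N = 50$. These sizes were chosen so each check completes in minutes on a
single core while keeping the Monte-Carlo margins (binomial 3σ,
Kolmogorov–Smirnov at 0.01) meaningful.
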