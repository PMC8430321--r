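---
title: "netpharm: model, parameters, and numerical decisions"
author: "netpharm maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netpharm: model, parameters, and numerical decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `netpharm`, the
default parameters and why they were chosen, how the synthetic
generators approximate real data, and the numerical and design decisions
that shape the implementation. It is a methods reference, not a
tutorial; see the README for a worked example.

## The model

The object of study is a multi-compound intervention (for example an
herbal formula) whose constituent compounds hit a set of protein targets
*T*, evaluated against a disease gene set *V* on an undirected
protein–protein interactome *G*. The chain makes four claims, each with
its own statistic:

1. **The targets are non-randomly close to the disease module.**
   Closest-distance proximity

   $$d_c(V, T) = \frac{1}{|T|} \sum_{t \in T} \min_{v \in V} d(v, t)$$

   with $d$ the hop distance on *G*, standardized as
   $z = (d_c - \mu)/\sigma$ against random set pairs matched to *V* and
   *T* in size and degree. The asymmetry (minimum over disease genes,
   mean over targets) is deliberate: it asks whether each *target* has a
   nearby disease gene, not the converse.

2. **Diffusion from the disease genes ranks mechanistic hubs.** Random
   walk with restart: $p_{t+1} = (1-r) M p_t + r\, p_0$, where
   $M_{ij} = A_{ij} / \deg(j)$ is the column-normalized adjacency and
   $p_0$ is uniform over the seed genes. The stationary $p$ is a
   seed-anchored centrality.

3. **The disease–target subnetwork has modular structure.** Greedy
   agglomerative modularity maximization over the subnetwork, with
   modularity $Q = \sum_c (e_{cc} - a_c^2)$, $e_{cc}$ the fraction of
   edges inside community $c$ and $a_c$ its fraction of edge endpoints.

4. **Clusters are functionally coherent.** One-sided hypergeometric
   over-representation of each cluster against a term collection, with
   Benjamini–Hochberg control of the false discovery rate across terms.

## Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| OB threshold (`obMin`) | 30 (%) | conventional ADME cut for orally active compounds; boundary values are retained (the test is `>=`) |
| DL threshold (`dlMin`) | 0.18 | conventional drug-likeness cut, same inclusive convention |
| restart probability `r` | 0.75 | strong anchoring to the seeds; with `r = 1` the walk provably returns the seed distribution, which the tests assert exactly |
| convergence `tol` | 1e-10 | L1 change between iterates; far below any decision threshold downstream, reached in tens of iterations on graphs of this size |
| `maxIter` | 10000 | safety bound; non-convergence raises a warning and is flagged on the result object |
| null replicates `nRandom` | 1000 | resolves z to roughly ±0.03 standard errors of the null mean; tests use 100 for speed, with correspondingly wider acceptance bands |
| `minSize` | 3 | communities below 3 genes are reported but flagged unclustered; a 2-gene "community" carries no modular evidence |
| `alpha` | 0.05 | significance on BH-adjusted p-values |
| degree-bin occupancy | 100 (or `max(10, n/10)` below 200 nodes) | bins grown from the lowest degree until each holds enough nodes to sample from without collapsing to near-deterministic draws |

Degree bins are grown upward over sorted degree values, all nodes
sharing a degree value land in the same bin, and the final bin absorbs
any remainder. A null replicate then redraws each set bin-by-bin with
the same per-bin counts as the observed set, so hub bias — the dominant
confounder of raw proximity — is controlled by construction.

## Numerical and design decisions

**Population σ.** The null standard deviation uses the population form
$\sigma = \sqrt{\tfrac{1}{n}\sum (d_i - \mu)^2}$, not the sample form:
the replicates *are* the null distribution being standardized against,
not a sample from which a variance is being estimated for inference.

**Degenerate nulls fail loudly.** When every replicate yields the same
distance (σ = 0, e.g. on a complete graph), `proximityZ()` raises a
typed `degenerateNullError` carrying the observed `dc` and null `mu`
rather than returning an infinite or NaN z.

**Disjointness of null pairs.** When the observed *V* and *T* are
disjoint, each null pair is kept disjoint too: `T_rand` is drawn
excluding `V_rand` (otherwise the two sets of a replicate are drawn
fully independently). Without this, overlapping null draws contribute
spurious zero distances, deflating μ and inflating σ — and the complete
graph example above would silently produce a finite z instead of the
degenerate-null error. The null thus mirrors the observed pair's overlap
structure. The sampler is injectable (`sampler` argument) for users who
want a different null.

**Unreachable targets.** Targets with no path to any disease gene are
excluded from the mean (their minimum is infinite) and counted in
`nDroppedTargets`, rather than poisoning $d_c$. Set members absent from
the graph are dropped with a warning before computation.

**Largest connected component.** The pipeline restricts loaded graphs
to their largest connected component by default (`useLCC = TRUE`):
proximity and diffusion across disconnected components are undefined or
vacuous. Ties between equal-sized components break to the one containing
the lexicographically smallest node, so the choice is deterministic.

**L1 convergence.** The walk's stopping rule is the L1 norm of the
iterate difference. Since iterates are probability vectors (mass 1 is
conserved exactly at every step, which the tests assert), L1 is the
natural metric and gives a scale-free threshold.

**Own greedy modularity.** Community detection is an in-package
Clauset–Newman–Moore implementation rather than a library call. Two
reasons: the contract requires deterministic tie-breaking (ties in
$\Delta Q$ break to the smallest community index; final labels are
0-based, ordered by decreasing size then smallest member), which
off-the-shelf implementations do not promise; and during validation the
library routine's dendrogram cut mis-selected the partition on small
graphs (returning a 2-community split of a clique whose best cut is the
single community). Merging stops when the best $\Delta Q \le$ 1e-14 —
numerically zero — so cliques end as one community with $Q$ exactly 0.
The $Q$ formula itself is cross-checked against an independent
implementation in the tests.

**Hypergeometric tail.** Enrichment p-values are
`phyper(k - 1, K, N - K, n, lower.tail = FALSE)` — the probability of
*k or more* successes — validated in the tests against exhaustive
enumeration of the hypergeometric mass for every configuration with
universe size ≤ 20. BH adjustment is the default; raw p-values are kept
in the output (and a `correction = "none"` mode exists) so calibration
can be checked on the uncorrected scale.

**Determinism.** Every stochastic entry point takes a seed (or uses the
session RNG explicitly, documented per function). The pipeline derives
all stage seeds from the single configuration seed, and repeated runs
produce byte-identical outputs apart from the manifest's timestamp.

## Synthetic data: realism and limits

`generateInteractome()` grows a connected scale-free graph by
preferential attachment: each new node attaches `attachM` edges to
existing nodes with probability proportional to degree + 1. This
reproduces the heavy-tailed degree distribution that makes
degree-matched nulls necessary in the first place. It does **not**
reproduce the high local clustering, community structure, or
degree–degree correlations of curated interactomes, so absolute z
magnitudes on synthetic graphs are not transferable to real data — only
the calibration (z approximately standard normal under the null) and
ordering properties are.

`plantPair()` plants a disease module as a BFS ball around a random
(or forced-hub) center, then constructs a target set a fraction `q` of
which lies within one hop of the module and the rest strictly outside
its closed neighborhood. `q` is therefore a planted effect size: `q = 0`
is a null pair, `q = 1` maximally proximal, and median z is expected to
decrease in `q` — which the acceptance tests and `scripts/acceptance.R`
verify empirically.

`generateCompoundTable()` emits compound records with exactly
`round(passFraction * n)` records passing the OB/DL screen, including
one record exactly at both boundaries, so screening can be validated
against an exact count. `generateTermCollection()` plants one term with
a controlled overlap against a designated query on top of uniformly
drawn background terms.

Validation problem sizes (2000-node graphs, 100–200 replicates, 100-node
oracle graphs) were chosen to keep the full suite within minutes while
leaving the statistical bands (null z mean within ±0.3, sd within
[0.7, 1.3], detection rates ≥ 0.9) comfortably wide relative to their
Monte-Carlo error at those sizes.

## Limitations

- Hop-count distances ignore edge confidences beyond the initial
  threshold filter; `loadEdgeList()` stores confidences but the
  proximity and walk operate on the unweighted graph.
- The degree-matched null controls degree and size only; it does not
  preserve the observed sets' internal connectivity or co-localization.
- Greedy modularity is a heuristic: on small graphs the tests bound its
  gap to the exhaustive optimum at 0.05, but no global guarantee exists,
  and modularity itself has a known resolution limit for very small
  communities.
- The hypergeometric model assumes a well-defined universe; results are
  sensitive to that choice, which is why `TermCollection` carries its
  universe explicitly and cross-collection comparisons refuse to mix
  universes.
- The screening thresholds (OB, DL) are conventional cut-offs, not
  optimized quantities; boundary inclusivity is a convention, documented
  and tested, not a scientific claim.
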