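---
title: "Agony, ranked block models, and the resolution of hierarchy detection"
author: "ragony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agony, ranked block models, and the resolution of hierarchy detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragony)
```

## The model

A ranking of a directed graph $G = (V, E)$ is an ordered partition of its
nodes: a map $r : V \to \{1, \dots, R\}$ into classes whose integer index is
their position in the hierarchy. An edge $(u, v)$ is *forward* when
$r(v) > r(u)$ and *backward* otherwise; same-class edges count as backward.
The *agony* of the ranking is

$$A_d(G, r) = \sum_{(u,v) \in E} f_d\big(r(u) - r(v)\big), \qquad
f_d(x) = \begin{cases} (x+1)^d & x \ge 0 \\ 0 & x < 0,\end{cases}$$

so a backward edge is charged more the further down the hierarchy it points,
and a same-class edge costs $f_d(0) = 1$ — without that offset the trivial
one-class ranking would always win. Minimising $A_d$ over all rankings gives
the graph's agony $A_d^*$ and its *hierarchy*
$h_d^* = 1 - A_d^*/m \in [0, 1]$: 1 for a DAG (a perfect hierarchy), 0 when
no ranking beats the trivial one. `agony()` is the fitting function;
`agony_value()` and `hierarchy_value()` evaluate fixed rankings, which need
not be optimal (their $h$ can then be negative).

## Solvers and their numerical choices

For $d = 1$ the objective per edge is $\max(0, r(u) - r(v) + 1)$, an LP in
the node potentials with a totally unimodular constraint matrix, so the LP
optimum is integral. Its dual is a maximum circulation with unit
capacities — the largest Eulerian subgraph. The `"flow"` method saturates
every edge at cost $-1$, repairs the node imbalances by successive shortest
paths with Johnson potentials (all in compiled code), and recovers optimal
ranks from Bellman–Ford distances in the residual network; the primal agony
is checked against the dual circulation value on every call. The solver
handles the sizes used throughout this package (thousands of nodes,
$10^4$–$10^5$ edges) in well under a second.

`"brute"` enumerates every ordered partition (restricted-growth strings
crossed with block-label permutations) and is the reference the flow solver
is validated against on hundreds of seeded small graphs and on every
tournament with four nodes. It is exact for *any* $d \ge 0$ but the ordered
Bell numbers cap it at 8 nodes by default. Co-optimal rankings are resolved
deterministically: fewest classes first, then the lexicographically
smallest rank vector over alphabetically sorted node names. The
fewest-classes preference follows the convention that among equal-agony
rankings the coarsest is reported; the lexicographic step merely makes
tests reproducible.

$d = 0$ is the minimum feedback arc set problem (NP-hard), so beyond the
brute-force range only a deterministic greedy heuristic is offered: remove
the node maximising out-degree minus in-degree, append it to a linear
order, and rank one node per class. The maximum of a quantity summing to
zero is non-negative, which yields the guarantee that backward edges never
exceed $m/2$; results carry a `heuristic` flag. No polynomial method is
attempted for other exponents — closed-form theory below covers
$d \in \{0, 1, 2\}$, and `agony()` says so rather than silently
approximating. Mixed-integer formulations were considered and set aside:
the exact flow solver plus enumeration already covers every case the
package's analyses need.

Gap-containing rank vectors are accepted when *evaluating* agony (the sum
is defined for any integer ranks) but canonicalised — relabelled to
consecutive integers, which can only lower agony — before and after
optimisation. Self-loops are rejected at graph construction: they would
add a constant $f_d(0) = 1$ each and pollute comparisons. The TSV reader
instead drops them (and duplicate edges) with a warning, so real-world
edge lists load.

## The Ranked Stochastic Block Model

`rsbm(p, q, s, R, n)` defines the generator that doubles as the package's
synthetic-data module. Nodes are split into $R$ ordered classes; each
ordered pair of distinct nodes carries an edge independently with
probability $c_{ij}$: $p$ one class up, $q$ further up, $s$ on and below
the diagonal. The planted ranking assigns class $i$ rank $i$. Two named
regimes recur: *twitter-like* ($p \ge q > s$, forward links to any higher
class) and *military-like* ($q = 0$, forward links only to the next class
up). The hierarchy constraint — expected backward links not exceeding
expected forward links — bounds the noise by $s_{\max}$ (see `s_max()`);
parameter sets beyond it warn rather than error because the sweep
experiments deliberately scan $s$ right up to the boundary.

Sampling draws one binomial count per block and places edges uniformly
without replacement inside the block, which is distributionally identical
to per-pair Bernoulli draws and much faster; reciprocal pairs across
classes can occur, as the independent-pair model dictates. A convention
detail that matters for reproducing printed numbers: the closed-form
theory uses the pair counts $b_k = \sum_i n_i n_{i+k}$ with
$b_0 = \sum_i n_i^2$, while the sampler's moments (`block_counts()`) use
the exact ordered distinct-pair count $n_i(n_i - 1)$ on the diagonal. The
difference is $O(1/n_i)$ and both are exposed (`convention` argument of
`expected_hierarchy()`).

What the generator does *not* emulate about real directed networks:
degree heterogeneity within classes, sparsity with hubs, reciprocity
beyond independence, and backward probabilities that decay with class
distance. Tests passing on RSBM draws therefore certify the solver and
the theory on block-homogeneous graphs, not recovery on heavy-tailed real
networks — on those, only the solver's exactness guarantee carries over.

## First-order theory and the resolution limit

The expected hierarchy of the planted ranking, to first order in the
block-count expectations, is

$$\bar h_d = 1 - \frac{s \sum_{k=0}^{R-1} (k+1)^d b_k}
{p\, b_1 + q \sum_{k \ge 2} b_k + s \sum_k b_k},$$

implemented for any $d$ and any class sizes (`planted_hierarchy()`);
the covariance corrections of the second-order expansion are deliberately
out of scope, as the first-order estimates already track simulations
closely. Candidate rankings derived from the planted one — merging
$2^b$ adjacent classes, splitting each class into $2^{-b}$ parts, and/or
inverting the order — have closed-form estimates for $d = 1, 2$
(`candidate_hierarchy()`, with real-valued $b$ for the continuous
uniform-class-number family). Every closed form is validated against an
independent expectation oracle (`expected_hierarchy()`) that sums
$E[m_{ij}] f_d(\tilde r_i - \tilde r_j)$ over block pairs directly; the
test suite requires agreement to $10^{-9}$ across a parameter grid, and
the closed forms are only trusted on that basis. The merge-family closed
forms do not extend to splits, so integer splits are routed through the
oracle.

Comparing candidates yields resolution thresholds
(`resolution_thresholds()`), derived from tie and zero-crossing
conditions in the continuous family and cross-checked against the oracle:

* twitter, $d = 1$: $s_m$ (the merged ranking with $R - 1$ classes ties
  the planted one — beyond it agony prefers coarser rankings), $s_2$
  (the merged family collapses to two classes), and the interior merge
  optimum $b^*$;
* military, $d = 1$: $s_i$ (the inverted two-class ranking ties the
  planted), $s_1$ (the planted estimate crosses zero), $s_3^i$ (inverted
  three classes overtake inverted two), and $b^{i,*}$;
* $d = 2$: the analogous set ($s_{2,m}, s_{2,1}$;
  $s_{2,1}^0, s_{2,2}^i, s_{2,3}^i = 3 s_{2,2}^i, b_2^{i,*}$), with the
  interior optimum $b_2^*$ computed numerically since it solves a cubic;
* $d = 0$: the optimum is always the fully split ranking, one node per
  class, with estimate at least $1/2$ for every valid parameter set.

The thresholds shrink as $R^{-2}$ ($d = 1$) and $R^{-3}$ ($d = 2$):
the more classes, the weaker the noise that already defeats detection —
the resolution limit, analogous to modularity's in community detection.
At the reference point $R = 32$, $p = 0.5$: $s_m = 0.00151$ (with
$q = 0.5$), and $s_i = 0.00280$, $s_1 = 0.00284$, $s_{\max} = 0.0294$
(with $q = 0$).

`optimal_candidate()` scans the integer candidate family with the oracle
and is cross-checked against the piecewise selections above; interior
real-valued optima are bracketed by their two nearest integers.

## Experiments at desk scale

`run_sweep()` reproduces the phase diagrams on sizes a laptop handles in
seconds per cell: the package's standard simulation conditions are
$R = 16$, $n = 16$ ($N = 256$) with a doubling grid in $s$ and a handful
of seeded replicates, while the analytic reference point $R = 32$,
$n = 128$ ($N = 4096$) is exercised through the closed forms, which cost
nothing to evaluate. One master seed is
split deterministically per (s, replicate) cell, so sweeps are exactly
reproducible. Recorded per cell: optimal hierarchy, inferred class count,
adjusted Rand index against the planted ranking, Kendall alignment
(`rank_alignment()`, whose sign separates faithful recovery from
inversion — ARI alone cannot, since a partition and its inversion have
ARI 1), and the theory overlays where closed forms apply.

The sweeps show the three predicted phases: perfect recovery at small
$s$; merging of adjacent classes past the threshold (the inferred class
count collapses towards 2, after a small bump of extra boundary classes
just above zero noise); and in the
military regime sign-flipping alignment as (partially) inverted rankings
take over. Partial inversions are expected: the symmetric candidate
family provides an upper bound on the true resolution threshold, not the
global optimum.

## Iterated agony

`iterated_agony()` re-optimises the subgraph induced by each first-pass
class to recover structure below the resolution limit. Defaults follow
the two-pass design of the experiments: `depth = 2`, `min_size = 4`, no
hierarchy-based stop. A stopping criterion is left configurable on
purpose: agony finds two classes even in an Erdős–Rényi graph, and high
sub-class counts with high sub-hierarchy mark splits that do not help, so
`stop_h` can freeze classes already resolved into at most two sub-classes
above a hierarchy threshold. Classes with no internal edges (every class
of a DAG's optimal ranking) are left unsplit. The refined ranking sorts
nodes by (parent rank, sub-rank); its global hierarchy is typically
*lower* than the first pass's optimum — the benefit is in recovery (ARI),
which is what the package's improvement test asserts, in the regime
around $3 s_m$ where merging has set in.

## Known limitations

* Exact optimisation beyond $d = 1$ is enumeration-limited; $0 < d < 1$
  (concave, NP-hard) has no heuristic here.
* Closed forms require uniform class sizes and $R = 2^a$; other
  configurations go through `planted_hierarchy()` (any sizes) or the
  oracle (uniform sizes, any integer split/merge).
* The candidate family is symmetric (uniform merges/splits, full
  inversion); partially inverted rankings are observed in simulations
  but have no analytic treatment here.
* Weighted, multi-, or undirected graphs are out of scope, as are
  degree-corrected block models and distance-dependent backward
  probabilities.
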